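#' Pairwise Jaccard similarity between modules
#'
#' `J[m1, m2] = |genes(m1) ∩ genes(m2)| / |genes(m1) ∪ genes(m2)|` over all
#' modules of all regions. Modules from the same region partition their genes,
#' so within-region off-diagonal entries are 0 (asserted).
#'
#' @param module_genes Named list, module id -> character vector of genes.
#'   Module ids are expected to carry the region prefix (`"L1-M1"`).
#' @return Symmetric J matrix in `[0, 1]` with unit diagonal.
#' @export
pairwise_jaccard <- function(module_genes) {
  assert_that(length(module_genes) >= 2, "need at least two modules")
  sizes <- lengths(module_genes)
  assert_that(all(sizes > 0), "empty module: %s",
              paste(names(module_genes)[sizes == 0], collapse = ", "))
  ids <- names(module_genes)
  k <- length(ids)
  J <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) {
    for (j in i:k) {
      inter <- length(intersect(module_genes[[i]], module_genes[[j]]))
      uni <- length(union(module_genes[[i]], module_genes[[j]]))
      J[i, j] <- J[j, i] <- inter / uni
    }
  }
  region_of <- sub("-M[0-9]+$", "", ids)
  same <- outer(region_of, region_of, `==`) & upper.tri(J)
  assert_that(all(J[same] == 0),
              "within-region modules overlap: partition violated")
  J
}

#' Component-wise maximum of within-region eigengene correlations
#'
#' For each region, the Pearson correlation matrix of all module eigengenes
#' over that region's spots is computed; `E` is the element-wise maximum over
#' regions. Entries that are missing in a region (constant ME there) are
#' ignored by the maximum; a pair missing in every region is an error.
#'
#' @param me Spots x modules ME matrix (all modules, all spots).
#' @param regions Per-spot region labels.
#' @param min_spots Minimum spots per region to include it.
#' @return Symmetric E matrix in `[-1, 1]` with unit diagonal.
#' @export
max_cross_correlation <- function(me, regions, min_spots = 3) {
  assert_that(length(regions) == nrow(me), "regions must label every spot")
  ids <- colnames(me)
  k <- length(ids)
  E <- matrix(-Inf, k, k, dimnames = list(ids, ids))
  for (r in unique(regions)) {
    idx <- regions == r
    if (sum(idx) < min_spots) next
    cc <- suppressWarnings(stats::cor(me[idx, , drop = FALSE]))
    cc[is.na(cc)] <- -Inf
    E <- pmax(E, cc)
  }
  if (any(!is.finite(E))) {
    bad <- which(!is.finite(E), arr.ind = TRUE)[1, ]
    stopf("eigengene correlation undefined in every region for pair (%s, %s)",
          ids[bad[1]], ids[bad[2]])
  }
  diag(E) <- 1
  E
}

#' Module-module dissimilarity for meta-module clustering
#'
#' `D = 1 - (E + 3 J) / 4`, a 1:3-weighted mean of the eigengene-correlation
#' and gene-overlap similarities, so that identical modules (`E = J = 1`)
#' have dissimilarity 0. The alternative literal parenthesization
#' `1 - (E + 3 J / 4)` is available via `literal = TRUE` for sensitivity
#' analysis; it can go negative and is not a dissimilarity.
#'
#' @param E,J Aligned module x module matrices.
#' @param literal Use the literal parenthesization.
#' @return Symmetric D matrix.
#' @export
meta_dissimilarity <- function(E, J, literal = FALSE) {
  assert_that(all(dim(E) == dim(J)), "E and J have different shapes")
  D <- if (literal) 1 - (E + 3 * J / 4) else 1 - (E + 3 * J) / 4
  (D + t(D)) / 2
}

#' Cluster modules into meta-modules
#'
#' Euclidean distances between the rows of `D`, agglomerative hierarchical
#' clustering, and a cut into exactly `k` clusters. Deterministic given `D`.
#'
#' @param D Module dissimilarity matrix from [meta_dissimilarity()].
#' @param k Number of meta-modules.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return List with `map` (named module -> `"meta-M<j>"`) and `tree` (the
#'   hclust object).
#' @export
cluster_metamodules <- function(D, k = 15, linkage = "average") {
  assert_that(k >= 1 && k <= nrow(D),
              "k must lie between 1 and the number of modules")
  tree <- stats::hclust(stats::dist(D), method = linkage)
  cl <- stats::cutree(tree, k = k)
  map <- stats::setNames(paste0("meta-M", cl), rownames(D))
  list(map = map, tree = tree)
}

#' Meta-module eigengenes
#'
#' First principal component over the union of member-module genes, with the
#' same standardization and sign rule as [module_eigengenes()].
#'
#' @param expr Observations x genes matrix.
#' @param module_genes Named list, module id -> genes.
#' @param meta_map Named module -> meta-module map from
#'   [cluster_metamodules()].
#' @return Observations x meta-modules ME matrix.
#' @export
metamodule_eigengenes <- function(expr, module_genes, meta_map) {
  metas <- sort(unique(meta_map))
  assign <- character()
  for (mm in metas) {
    genes <- unique(unlist(module_genes[names(meta_map)[meta_map == mm]]))
    genes <- intersect(genes, colnames(expr))
    assign[genes] <- mm # a gene in several metas keeps the last; ME uses union per meta below
  }
  # build MEs per meta over its own union (genes may appear in several metas)
  n <- nrow(expr)
  me <- matrix(0, n, length(metas), dimnames = list(rownames(expr), metas))
  for (mm in metas) {
    genes <- unique(unlist(module_genes[names(meta_map)[meta_map == mm]]))
    genes <- intersect(genes, colnames(expr))
    assert_that(length(genes) >= 2, "meta-module %s has < 2 genes", mm)
    tmp <- stats::setNames(rep(mm, length(genes)), genes)
    me[, mm] <- module_eigengenes(expr, tmp)[, mm]
  }
  me
}

#' Re-assign genes claimed by several meta-modules
#'
#' A gene inherits the meta-module of its module; a gene belonging to modules
#' of different meta-modules (module overlap across regions) is re-assigned
#' to the meta-module where it has the highest eigengene-based connectivity.
#' Exact kME ties break to the lexicographically smallest meta-module id.
#'
#' @param module_genes Named list, module id -> genes.
#' @param meta_map Named module -> meta-module map.
#' @param kme_meta Genes x meta-modules kME matrix (correlation with
#'   meta-module eigengenes).
#' @return Named character vector gene -> meta-module; genes with missing kME
#'   in all claimed meta-modules are `"unassigned"` and listed in the
#'   `"unassigned"` attribute.
#' @export
assign_genes_to_metamodules <- function(module_genes, meta_map, kme_meta) {
  claims <- list()
  for (m in names(meta_map)) {
    for (g in module_genes[[m]]) {
      claims[[g]] <- union(claims[[g]], meta_map[[m]])
    }
  }
  genes <- names(claims)
  out <- stats::setNames(character(length(genes)), genes)
  unresolved <- character()
  for (g in genes) {
    cand <- sort(claims[[g]])
    if (length(cand) == 1L) { out[g] <- cand; next }
    kv <- if (g %in% rownames(kme_meta)) kme_meta[g, cand] else rep(NA_real_, length(cand))
    if (all(is.na(kv))) {
      out[g] <- "unassigned"
      unresolved <- c(unresolved, g)
      next
    }
    best <- max(kv, na.rm = TRUE)
    out[g] <- cand[which(!is.na(kv) & kv == best)][1L] # cand sorted: ties lexicographic
  }
  attr(out, "unassigned") <- unresolved
  out
}

#' Differential module-eigengene (DME) test
#'
#' Per module (ME column), a two-sided Wilcoxon rank-sum test comparing ME
#' values between two groups within a region, with effect size the difference
#' of group means and Benjamini-Hochberg FDR across all tests of the
#' contrast family. Region-specific modules are tested only in their home
#' region when `module_home` is given; meta-modules (absent from
#' `module_home`) are tested in every region.
#'
#' @param me Observations x modules ME matrix.
#' @param group Per-observation group labels (exactly two used).
#' @param contrast Character vector of length 2: `c(group1, group2)`; effect
#'   = mean(ME | group1) - mean(ME | group2).
#' @param regions Per-observation region labels, or `NULL` for a single
#'   pooled test per module.
#' @param module_home Optional named module -> home-region map.
#' @param min_n Minimum observations per group per test.
#' @return `DMEResult` data frame: `module`, `region`, `contrast`, `effect`,
#'   `p`, `fdr`, `n1`, `n2`.
#' @export
dme_test <- function(me, group, contrast, regions = NULL,
                     module_home = NULL, min_n = 3) {
  assert_that(length(group) == nrow(me), "group must label every observation")
  assert_that(length(contrast) == 2, "contrast must name two groups")
  if (is.null(regions)) regions <- rep("all", nrow(me))
  rows <- list()
  for (m in colnames(me)) {
    test_regions <- if (!is.null(module_home) && m %in% names(module_home)) {
      module_home[[m]]
    } else unique(regions)
    for (r in test_regions) {
      i1 <- regions == r & group == contrast[1]
      i2 <- regions == r & group == contrast[2]
      if (sum(i1) < min_n || sum(i2) < min_n) next
      x1 <- me[i1, m]; x2 <- me[i2, m]
      p <- suppressWarnings(stats::wilcox.test(x1, x2)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, region = r,
        contrast = paste(contrast, collapse = " vs "),
        effect = mean(x1) - mean(x2), p = p,
        n1 = sum(i1), n2 = sum(i2), stringsAsFactors = FALSE)
    }
  }
  assert_that(length(rows) > 0, "no module/region had both groups at min_n")
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("module", "region", "contrast", "effect", "p", "fdr", "n1", "n2")]
}

#' Correlate module eigengenes with an external per-observation score
#'
#' Pearson correlation of each ME column with `scores`, within each group of
#' `groupby`; groups with fewer than three observations are skipped, and a
#' constant score within a group yields `NA`.
#'
#' @param me Observations x modules ME matrix.
#' @param scores Per-observation numeric scores (e.g. polygenic disease
#'   enrichment scores).
#' @param groupby Per-observation group labels, or `NULL` for one group.
#' @return Data frame: `module`, `group`, `r`, `n`.
#' @export
correlate_scores <- function(me, scores, groupby = NULL) {
  assert_that(length(scores) == nrow(me), "scores must align to observations")
  if (is.null(groupby)) groupby <- rep("all", nrow(me))
  rows <- list()
  for (g in unique(groupby)) {
    idx <- groupby == g
    if (sum(idx) < 3) next
    s <- scores[idx]
    for (m in colnames(me)) {
      r <- if (stats::sd(s) == 0) NA_real_ else {
        suppressWarnings(stats::cor(me[idx, m], s))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, group = g, r = r, n = sum(idx),
        stringsAsFactors = FALSE)
    }
  }
  assert_that(length(rows) > 0, "no group had >= 3 observations")
  do.call(rbind, rows)
}
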