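#' Filter genes by expression prevalence within spatial regions
#'
#' A gene is retained when, in at least one region, the fraction of spots
#' with count > 0 is at least `min_frac` (boundary inclusive: exactly 5%
#' passes at the default).
#'
#' @param counts Genes x spots count matrix.
#' @param groups Per-spot region labels.
#' @param min_frac Minimum within-region detection fraction.
#' @return Character vector of retained gene ids.
#' @export
filter_expressed_genes <- function(counts, groups, min_frac = 0.05) {
  assert_that(length(groups) == ncol(counts),
              "groups must label every spot")
  keep <- rep(FALSE, nrow(counts))
  for (r in unique(groups)) {
    idx <- groups == r
    frac <- rowMeans(counts[, idx, drop = FALSE] > 0)
    keep <- keep | frac >= min_frac
  }
  rownames(counts)[keep]
}

#' Pseudobulk log2-CPM profiles per (sample, region)
#'
#' Sums UMI over the spots of each (sample, region) pair, converts to counts
#' per million over the retained genes, and returns
#' `log2(CPM + pseudocount)`. Rows with zero total UMI are dropped with a
#' warning.
#'
#' @param counts Genes x spots count matrix (retained genes only).
#' @param sample_ids,regions Per-spot sample and region labels.
#' @param pseudocount Added inside the log2.
#' @return A `pseudobulk` matrix: rows = (sample, region) pairs (rownames
#'   `"sample|region"`), columns = genes; attributes `sample` and `region`
#'   hold the per-row tags.
#' @export
pseudobulk_log2cpm <- function(counts, sample_ids, regions, pseudocount = 1) {
  assert_that(length(sample_ids) == ncol(counts) &&
                length(regions) == ncol(counts),
              "sample_ids and regions must label every spot")
  key <- paste(sample_ids, regions, sep = "|")
  agg <- t(rowsum(t(counts), group = key)) # genes x groups
  tot <- colSums(agg)
  if (any(tot == 0)) {
    warnf("dropping %d pseudobulk row(s) with zero total UMI", sum(tot == 0))
    agg <- agg[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  cpm <- sweep(agg, 2L, tot, `/`) * 1e6
  out <- t(log2(cpm + pseudocount))
  parts <- strsplit(rownames(out), "|", fixed = TRUE)
  attr(out, "sample") <- vapply(parts, `[[`, character(1), 1L)
  attr(out, "region") <- vapply(parts, `[[`, character(1), 2L)
  class(out) <- c("pseudobulk", class(out))
  out
}

# adjacency from an expression matrix (observations x genes)
.adjacency <- function(expr, power, network_type = c("signed", "unsigned")) {
  network_type <- match.arg(network_type)
  cc <- stats::cor(expr)
  if (network_type == "signed") ((1 + cc) / 2)^power else abs(cc)^power
}

# signed scale-free topology fit index on equal-count connectivity bins;
# equal-count bins need the width-normalized density, not the raw bin
# probability (which is constant by construction)
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  breaks <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 4) return(NA_real_)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  width <- diff(breaks)
  p <- (as.numeric(table(bin)) / length(k)) / width
  ok <- p > 0 & is.finite(dk) & dk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(p[ok]) ~ log10(dk[ok]))
  -sign(stats::coef(fit)[2]) * summary(fit)$r.squared
}

#' Select the soft-thresholding power for a scale-free network
#'
#' For each candidate power, builds the signed (or unsigned) adjacency from
#' the gene-gene Pearson correlations of `expr`, computes connectivity
#' \eqn{k_i = \sum_{j \ne i} a_{ij}}, and evaluates the signed scale-free
#' fit index \eqn{-\mathrm{sign}(slope) R^2} of the regression of
#' `log10 p(k)` on `log10 k` over equal-count bins. The chosen power is the
#' smallest with fit above `threshold`; when none passes, the power with
#' maximal fit is returned with `passed = FALSE`.
#'
#' @param expr Observations x genes matrix (pseudobulk log2-CPM profiles).
#' @param candidate_powers Integer vector of powers to scan.
#' @param threshold Scale-free fit threshold.
#' @param network_type `"signed"` or `"unsigned"`.
#' @return A `network_config` list: `chosen_power`, `passed`, `fit` (per
#'   power), `candidate_powers`, `network_type`.
#' @export
select_soft_power <- function(expr, candidate_powers = c(1:10, seq(12, 20, 2)),
                              threshold = 0.8,
                              network_type = c("signed", "unsigned")) {
  network_type <- match.arg(network_type)
  assert_that(nrow(expr) >= 4, "need at least 4 observations")
  fits <- vapply(candidate_powers, function(p) {
    a <- .adjacency(expr, p, network_type)
    k <- colSums(a) - diag(a)
    scale_free_fit(k)
  }, numeric(1))
  pass <- which(!is.na(fits) & fits > threshold)
  if (length(pass) > 0) {
    chosen <- candidate_powers[pass[1]]
    passed <- TRUE
  } else {
    chosen <- candidate_powers[which.max(fits)]
    passed <- FALSE
  }
  structure(list(chosen_power = chosen, passed = passed,
                 fit = stats::setNames(fits, candidate_powers),
                 candidate_powers = candidate_powers,
                 network_type = network_type),
            class = "network_config")
}

#' Topological overlap matrix
#'
#' \deqn{TOM_{ij} = \frac{\sum_u a_{iu} a_{uj} + a_{ij}}
#'   {\min(k_i, k_j) + 1 - a_{ij}}, \quad TOM_{ii} = 1}
#' with \eqn{k_i = \sum_{j \ne i} a_{ij}}. Constant genes (non-finite
#' correlations) are dropped with a warning.
#'
#' @param expr Observations x genes matrix.
#' @param power Soft-thresholding power.
#' @param network_type `"signed"` (default) or `"unsigned"`.
#' @return Symmetric TOM with entries in `[0, 1]`, gene dimnames.
#' @export
tom_matrix <- function(expr, power, network_type = c("signed", "unsigned")) {
  network_type <- match.arg(network_type)
  assert_that(ncol(expr) >= 2, "need at least 2 genes")
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant gene(s)", sum(sds == 0))
    expr <- expr[, sds > 0, drop = FALSE]
  }
  a <- .adjacency(expr, power, network_type)
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- list(colnames(expr), colnames(expr))
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`
#' with a static cut at `cut_height`; clusters smaller than
#' `min_module_size` become unassigned (`"grey"`). Detected modules are then
#' merged iteratively: module eigengenes are computed on `expr` and any pair
#' with eigengene correlation above `1 - merge_height` is merged until none
#' remains.
#'
#' @param tom TOM from [tom_matrix()].
#' @param expr Observations x genes matrix used for eigengene-based merging.
#' @param min_module_size Minimum genes per module.
#' @param merge_height Eigengene merge cut height (modules merge when
#'   `cor(ME1, ME2) > 1 - merge_height`).
#' @param cut_height Static tree cut height on `1 - TOM` dissimilarity.
#' @return Named character vector gene -> module (`"M1"`, `"M2"`, ... by
#'   decreasing size; `"grey"` = unassigned).
#' @export
detect_modules <- function(tom, expr, min_module_size = 50,
                           merge_height = 0.1, cut_height = 0.995) {
  genes <- rownames(tom)
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  tab <- table(cl)
  keep <- names(tab)[tab >= min_module_size]
  lab <- rep("grey", length(cl))
  names(lab) <- genes
  if (length(keep) == 0) {
    warnf("no module reached min_module_size = %d; all genes unassigned",
          min_module_size)
    return(lab)
  }
  # rank by size for stable naming
  keep <- keep[order(-tab[keep])]
  for (i in seq_along(keep)) lab[cl == as.integer(keep[i])] <- paste0("M", i)

  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(expr, lab)
    cc <- stats::cor(me)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[top[1], top[2]] <= 1 - merge_height) break
    m1 <- colnames(cc)[top[1]]; m2 <- colnames(cc)[top[2]]
    lab[lab == m2] <- m1
  }
  # re-rank names by size after merging
  mods <- setdiff(unique(lab), "grey")
  mods <- mods[order(-table(factor(lab, levels = mods))[mods])]
  out <- lab
  for (i in seq_along(mods)) out[lab == mods[i]] <- paste0("M", i)
  out
}

#' Module eigengenes
#'
#' Per module, the first principal component of the column-standardized
#' expression of its genes across observations, scaled to unit variance.
#' The sign is fixed so that the eigengene correlates non-negatively with
#' the mean standardized expression of the module genes, which makes results
#' reproducible across linear-algebra backends.
#'
#' @param expr Observations x genes matrix.
#' @param assignments Named character vector gene -> module (`"grey"`/
#'   `"none"` ignored). Genes absent from `expr` are dropped.
#' @return Observations x modules ME matrix (module names as colnames).
#'   A module whose genes are all constant gets an all-zero column, flagged
#'   via the `"degenerate"` attribute.
#' @export
module_eigengenes <- function(expr, assignments) {
  mods <- setdiff(unique(assignments), c("grey", "none"))
  assert_that(length(mods) > 0, "no modules in assignments")
  mods <- sort(mods)
  n <- nrow(expr)
  me <- matrix(0, n, length(mods), dimnames = list(rownames(expr), mods))
  degenerate <- character()
  for (m in mods) {
    genes <- intersect(names(assignments)[assignments == m], colnames(expr))
    assert_that(length(genes) >= 2, "module %s has < 2 genes in expr", m)
    sub <- expr[, genes, drop = FALSE]
    sds <- apply(sub, 2L, stats::sd)
    if (all(sds == 0)) { degenerate <- c(degenerate, m); next }
    sub <- sub[, sds > 0, drop = FALSE]
    z <- scale(sub)
    sv <- svd(z, nu = 1, nv = 0)
    pc <- sv$u[, 1]
    pc <- pc / stats::sd(pc)
    ref <- rowMeans(z)
    if (stats::sd(ref) > 0 && stats::cor(pc, ref) < 0) pc <- -pc
    me[, m] <- pc
  }
  attr(me, "degenerate") <- degenerate
  me
}

#' Eigengene-based connectivity (kME)
#'
#' `kME[g, m] = cor(expression of g, ME of m)` (Pearson), over aligned
#' observations. Constant genes get `NA`.
#'
#' @param expr Observations x genes matrix.
#' @param me Observations x modules ME matrix.
#' @return Genes x modules kME matrix in `[-1, 1]`.
#' @export
module_kme <- function(expr, me) {
  assert_that(nrow(expr) == nrow(me), "expr and ME have different observations")
  suppressWarnings(stats::cor(expr, me))
}

#' Project module eigengenes into a query dataset
#'
#' Recomputes each module's eigengene on the query expression restricted to
#' the module's genes, with the same standardization and sign rule. Modules
#' with fewer than two genes present in the query are skipped and reported.
#'
#' @param assignments Named character vector gene -> module.
#' @param query_expr Observations x genes matrix of the query dataset.
#' @return ME matrix over the query observations; skipped modules listed in
#'   the `"skipped"` attribute.
#' @export
project_modules <- function(assignments, query_expr) {
  mods <- setdiff(unique(assignments), c("grey", "none"))
  present <- vapply(mods, function(m) {
    sum(names(assignments)[assignments == m] %in% colnames(query_expr))
  }, numeric(1))
  skipped <- mods[present < 2]
  keep <- assignments[assignments %in% mods[present >= 2] &
                        names(assignments) %in% colnames(query_expr)]
  assert_that(length(keep) > 0, "no module has >= 2 genes in the query")
  me <- module_eigengenes(query_expr, keep)
  attr(me, "skipped") <- skipped
  me
}

#' Merge adjacent spots into meta-spots
#'
#' Groups spots by `(floor(array_row / b), floor(array_col / b))`, sums their
#' counts, places the meta-spot at the member centroid and labels it with the
#' majority region (ties broken by the lexicographically smallest label).
#' Used to densify sparse lattices before network analysis.
#'
#' @param grid A `spot_grid`.
#' @param counts Genes x spots count matrix aligned to the grid.
#' @param bin_width_spots Bin width `b` in lattice units; `b = 1` is the
#'   identity.
#' @return List with `grid` (meta-spot `spot_grid`) and `counts` (summed
#'   genes x meta-spots matrix). Total UMI is conserved.
#' @export
make_metaspots <- function(grid, counts, bin_width_spots = 2L) {
  b <- as.integer(bin_width_spots)
  assert_that(b >= 1, "bin_width_spots must be >= 1")
  key <- paste(grid$array_row %/% b, grid$array_col %/% b, sep = "_")
  agg <- t(rowsum(t(counts), group = key))
  groups <- split(seq_len(nrow(grid)), key)
  ids <- names(groups)
  meta <- data.frame(
    barcode = sprintf("%s_meta_%s", grid$sample_id[1L], ids),
    array_row = vapply(groups, function(i) min(grid$array_row[i]) %/% b, integer(1)),
    array_col = vapply(groups, function(i) min(grid$array_col[i]) %/% b, integer(1)),
    x_um = vapply(groups, function(i) mean(grid$x_um[i]), numeric(1)),
    y_um = vapply(groups, function(i) mean(grid$y_um[i]), numeric(1)),
    region = vapply(groups, function(i) lex_mode(grid$region[i]), character(1)),
    sample_id = grid$sample_id[1L],
    stringsAsFactors = FALSE
  )
  ord <- match(ids, colnames(agg))
  agg <- agg[, ord, drop = FALSE]
  colnames(agg) <- meta$barcode
  attr(meta, "spacing_um") <- attr(grid, "spacing_um") * b
  attr(meta, "diameter_um") <- attr(grid, "diameter_um")
  class(meta) <- c("spot_grid", "data.frame")
  rownames(meta) <- NULL
  list(grid = meta, counts = agg)
}

#' Consensus topological overlap across regions
#'
#' Each TOM (restricted to the shared gene set) is quantile-scaled to the
#' first by matching 95th percentiles, then the element-wise minimum is
#' taken — the classical consensus construction at consensus quantile 0.
#'
#' @param toms List of TOM matrices with gene dimnames.
#' @return Consensus TOM over the gene intersection. With a single TOM the
#'   input is passed through with a warning.
#' @export
consensus_tom <- function(toms) {
  assert_that(length(toms) >= 1, "need at least one TOM")
  if (length(toms) < 2) {
    warnf("single TOM: consensus is the identity passthrough")
    return(toms[[1]])
  }
  genes <- Reduce(intersect, lapply(toms, rownames))
  assert_that(length(genes) >= 2, "gene intersection across TOMs is < 2")
  toms <- lapply(toms, function(m) m[genes, genes])
  ref_q <- stats::quantile(toms[[1]][upper.tri(toms[[1]])], 0.95)
  scaled <- lapply(toms, function(m) {
    q <- stats::quantile(m[upper.tri(m)], 0.95)
    if (q > 0) m * (ref_q / q) else m
  })
  out <- Reduce(pmin, scaled)
  diag(out) <- 1
  out
}

#' Build a region-wise co-expression network
#'
#' Convenience wrapper for one region: soft-power selection, TOM, module
#' detection, MEs and kME on the region pseudobulk, with modules named
#' `"<region>-M<k>"`.
#'
#' @param pb A [pseudobulk_log2cpm()] matrix for all regions.
#' @param region Region to model (rows with this region tag are used).
#' @param candidate_powers,threshold,network_type Passed to
#'   [select_soft_power()].
#' @param min_module_size,merge_height,cut_height Passed to
#'   [detect_modules()].
#' @param power Optional fixed power (skips selection).
#' @return A `module_set` list: `region`, `power`, `assignments` (named
#'   gene -> `"<region>-M<k>"`, `"grey"` unassigned), `me`, `kme`, `genes`.
#' @export
build_region_network <- function(pb, region,
                                 candidate_powers = c(1:10, seq(12, 20, 2)),
                                 threshold = 0.8,
                                 network_type = "signed",
                                 min_module_size = 50, merge_height = 0.1,
                                 cut_height = 0.995, power = NULL) {
  rows <- attr(pb, "region") == region
  assert_that(sum(rows) >= 4, "region %s has < 4 pseudobulk rows", region)
  expr <- pb[rows, , drop = FALSE]
  if (is.null(power)) {
    cfg <- select_soft_power(expr, candidate_powers, threshold, network_type)
    power <- cfg$chosen_power
  }
  tom <- tom_matrix(expr, power, network_type)
  lab <- detect_modules(tom, expr, min_module_size, merge_height, cut_height)
  named <- lab
  named[lab != "grey"] <- paste0(region, "-", lab[lab != "grey"])
  if (all(lab == "grey")) {
    return(structure(list(region = region, power = power, assignments = named,
                          me = NULL, kme = NULL, genes = names(named)),
                     class = "module_set"))
  }
  me <- module_eigengenes(expr, named)
  kme <- module_kme(expr, me)
  structure(list(region = region, power = power, assignments = named,
                 me = me, kme = kme, genes = names(named), tom = tom),
            class = "module_set")
}
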