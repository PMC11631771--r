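#' Effective spot radius for binary assignment
#'
#' The nominal 55 um spot leaves a gap to its neighbours on the 100 um
#' lattice; the assignment radius is therefore expanded to half the lattice
#' pitch so that every binary near the lattice lands in at least one spot
#' while double assignment stays rare. An explicit `override` replaces the
#' rule.
#'
#' @param grid A `spot_grid` with a `spacing_um` attribute.
#' @param override Optional radius in micrometers.
#' @return Radius in micrometers.
#' @export
effective_radius <- function(grid, override = NULL) {
  if (!is.null(override)) {
    assert_that(is.numeric(override) && override > 0, "override must be > 0")
    return(override)
  }
  spacing <- attr(grid, "spacing_um")
  assert_that(is.numeric(spacing) && length(spacing) == 1 && spacing > 0,
              "grid spacing_um must be positive")
  spacing / 2
}

#' Assign amyloid binaries to spots and accumulate per-spot scores
#'
#' A binary is assigned to a spot when the circles intersect:
#' `dist(center_spot, center_binary) <= effective_radius + diameter/2`. A
#' binary intersecting several spots contributes to all of them.
#'
#' @param grid A `spot_grid` (one sample).
#' @param binaries An `amyloid_binaries` table for the same sample, one stain.
#' @param radius_override Optional effective radius (see
#'   [effective_radius()]).
#' @return Data frame with one row per spot: `barcode`, `n_binaries`,
#'   `total_area_um2`.
#' @export
score_spots <- function(grid, binaries, radius_override = NULL) {
  stopifnot(inherits(grid, "spot_grid"))
  r <- effective_radius(grid, radius_override)
  n <- nrow(grid)
  nb <- integer(n); area <- numeric(n)
  if (nrow(binaries) > 0) {
    assert_that(length(unique(binaries$stain)) <= 1,
                "score one stain at a time")
    if (!is.null(binaries$sample_id) && nrow(binaries) > 0) {
      assert_that(all(binaries$sample_id == grid$sample_id[1L]),
                  "binaries and grid are from different samples")
    }
    for (i in seq_len(nrow(binaries))) {
      d <- sqrt((grid$x_um - binaries$x_um[i])^2 +
                  (grid$y_um - binaries$y_um[i])^2)
      hit <- d <= r + binaries$diameter_um[i] / 2
      nb[hit] <- nb[hit] + 1L
      area[hit] <- area[hit] + binaries$area_um2[i]
    }
  }
  data.frame(barcode = grid$barcode, n_binaries = nb,
             total_area_um2 = area, stringsAsFactors = FALSE)
}

#' Build the unweighted neighbour graph of a spot lattice
#'
#' Spots are neighbours when their center distance is at most
#' `spacing_um * (1 + tol)`; on a regular hexagonal lattice interior spots
#' have six neighbours. Self-loops are not stored (the Gi* self-weight is
#' added analytically).
#'
#' @param grid A `spot_grid`.
#' @param tol Relative distance tolerance.
#' @return A symmetric sparse logical adjacency matrix
#'   (spots x spots, barcodes as dimnames).
#' @export
build_neighbor_graph <- function(grid, tol = 0.05) {
  stopifnot(inherits(grid, "spot_grid"))
  assert_that(nrow(grid) >= 1, "grid must be non-empty")
  spacing <- attr(grid, "spacing_um")
  d <- pair_dist(cbind(grid$x_um, grid$y_um))
  adj <- d <= spacing * (1 + tol)
  diag(adj) <- FALSE
  dimnames(adj) <- list(grid$barcode, grid$barcode)
  Matrix::Matrix(adj, sparse = TRUE)
}

#' Getis-Ord Gi* hotspot statistic
#'
#' For each spot i with binary weights \eqn{w_{ij} = 1} for j in
#' neighbours(i) and for j = i (self-inclusion, the "star" variant), 0
#' otherwise:
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar X W_i}
#'   {S \sqrt{(n \sum_j w_{ij}^2 - W_i^2) / (n - 1)}}}
#' with \eqn{W_i = \sum_j w_{ij}}, \eqn{\bar X} the global mean and
#' \eqn{S = \sqrt{\sum_j x_j^2 / n - \bar X^2}} the population standard
#' deviation.
#'
#' @param scores Numeric per-spot values, aligned to the graph.
#' @param graph Adjacency matrix from [build_neighbor_graph()] (no
#'   self-loops).
#' @return Numeric vector of Gi* z-values.
#' @section Degenerate fields: a constant score vector has S = 0 and raises
#'   an error of class `spotnet_degenerate_field`; callers typically skip the
#'   stain or sample (for example wild-type tissue with no amyloid).
#' @export
gi_star <- function(scores, graph) {
  n <- length(scores)
  assert_that(n >= 2, "need at least two spots")
  assert_that(nrow(graph) == n && ncol(graph) == n,
              "graph and scores have different sizes")
  xbar <- mean(scores)
  s <- sqrt(sum(scores^2) / n - xbar^2)
  if (s == 0) {
    stopf("constant score field: Gi* undefined (S = 0)",
          class = "spotnet_degenerate_field")
  }
  a <- Matrix::Matrix(graph * 1, sparse = TRUE)
  wi <- Matrix::rowSums(a) + 1           # W_i, binary weights incl. self
  num <- as.numeric(a %*% scores) + scores - xbar * wi
  denom <- s * sqrt((n * wi - wi^2) / (n - 1)) # sum w^2 = W_i for 0/1 weights
  as.numeric(num / denom)
}

#' Log1p-CPM normalization of a counts matrix
#'
#' `log1p(1e6 * count / total_umi)` per spot; the normalization used for the
#' Pearson-correlation filter of the amyloid gene caller.
#'
#' @param counts Genes x spots count matrix.
#' @return Matrix of the same shape.
#' @export
normalize_log1p_cpm <- function(counts) {
  tot <- colSums(counts)
  assert_that(all(tot > 0), "spot with zero total UMI")
  log1p(sweep(counts, 2L, tot, `/`) * 1e6)
}

#' Per-gene GLM of spot counts on an amyloid score
#'
#' Fits, for each gene, a log-link count regression of UMI on the per-spot
#' amyloid score with sample of origin (categorical) and `log(total UMI + 1)`
#' as covariates, and returns the score coefficient with its standard error
#' and two-sided Wald p value. The default family is quasi-Poisson (moment
#' estimate of the dispersion); `family = "nb"` refits with a negative
#' binomial (needs \pkg{MASS}).
#'
#' Redundant design columns (e.g. the sample factor when only one sample is
#' included) are dropped with a warning. Genes with all-zero counts on the
#' included spots are skipped with a reason code; genes whose fit fails
#' (e.g. separation) return `NA` with a reason.
#'
#' @param counts Genes x spots count matrix.
#' @param score Per-spot numeric score (Gi* field or standardized amyloid
#'   area), aligned to the columns of `counts`.
#' @param sample Per-spot sample ids (categorical covariate), or `NULL`.
#' @param include Logical per-spot filter (e.g. grey-matter spots only);
#'   `NULL` keeps all spots.
#' @param family `"quasipoisson"` (default) or `"nb"`.
#' @param log_size Optional per-spot numeric sequencing-depth covariate
#'   replacing the default `log(total UMI + 1)`. Supplying the log of a
#'   known library-size factor removes the endogeneity that the observable
#'   total-UMI proxy has when few genes are measured (calibration studies);
#'   on real data the default proxy is appropriate.
#' @return Data frame with one row per gene: `gene`, `beta`, `se`, `wald_p`,
#'   `reason` (`"ok"`, `"all_zero"`, or `"fit_failed"`).
#' @export
amyloid_glm <- function(counts, score, sample = NULL, include = NULL,
                        family = c("quasipoisson", "nb"), log_size = NULL) {
  family <- match.arg(family)
  n_spots <- ncol(counts)
  assert_that(length(score) == n_spots, "score length != number of spots")
  if (is.null(include)) include <- rep(TRUE, n_spots)
  assert_that(length(include) == n_spots, "include length != number of spots")
  assert_that(all(is.finite(score[include])),
              "score must be finite on included spots")

  y_all <- counts[, include, drop = FALSE]
  x <- score[include]
  log_umi <- if (is.null(log_size)) log(colSums(y_all) + 1) else {
    assert_that(length(log_size) == n_spots,
                "log_size length != number of spots")
    log_size[include]
  }
  df <- data.frame(score = x, log_umi = log_umi)
  if (!is.null(sample)) {
    s <- factor(sample[include])
    if (nlevels(s) > 1) df$sample <- s
  }
  X <- stats::model.matrix(~ ., df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warnf("dropping %d redundant design column(s): %s",
          ncol(X) - qrX$rank,
          paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  j <- which(colnames(X) == "score")
  assert_that(length(j) == 1, "score column dropped: design is degenerate")

  genes <- rownames(counts)
  res <- data.frame(gene = genes, beta = NA_real_, se = NA_real_,
                    wald_p = NA_real_, reason = "ok",
                    stringsAsFactors = FALSE)
  for (g in seq_along(genes)) {
    y <- y_all[g, ]
    if (all(y == 0)) { res$reason[g] <- "all_zero"; next }
    fit <- tryCatch({
      if (family == "quasipoisson") {
        f <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
        mu <- f$fitted.values
        dfres <- length(y) - f$rank
        disp <- sum((y - mu)^2 / mu) / dfres
        R <- qr.R(f$qr)
        cov_unscaled <- chol2inv(R)
        piv <- f$qr$pivot
        se_all <- numeric(ncol(X))
        se_all[piv] <- sqrt(disp * diag(cov_unscaled))
        list(beta = f$coefficients[j], se = se_all[j])
      } else {
        if (!requireNamespace("MASS", quietly = TRUE)) {
          stopf("family = 'nb' needs the MASS package")
        }
        f <- suppressWarnings(MASS::glm.nb(y ~ X - 1))
        sm <- summary(f)$coefficients
        list(beta = sm[j, 1], se = sm[j, 2])
      }
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$beta) || !is.finite(fit$se) ||
        fit$se <= 0) {
      res$reason[g] <- "fit_failed"
      next
    }
    res$beta[g] <- fit$beta
    res$se[g] <- fit$se
    res$wald_p[g] <- 2 * stats::pnorm(-abs(fit$beta / fit$se))
  }
  res
}

#' Call amyloid-associated genes
#'
#' Applies Benjamini-Hochberg FDR over all tested genes within the analysis
#' unit and computes, per gene, the Pearson correlation of log1p-CPM
#' normalized expression with the amyloid score over the included spots. A
#' gene is amyloid-associated iff `fdr < alpha` and `pearson_r > 0`.
#'
#' @param glm_results Output of [amyloid_glm()].
#' @param counts Genes x spots count matrix (same genes).
#' @param score Per-spot score used in the GLM.
#' @param include Logical per-spot filter, as passed to [amyloid_glm()].
#' @param alpha FDR threshold in (0, 1).
#' @param unit Analysis-unit label recorded on every row (pooled GM for the
#'   human analysis, a cluster id for the mouse analysis).
#' @param stain Stain label recorded on every row.
#' @return `AmyloidGeneResult` data frame: `gene`, `stain`, `analysis_unit`,
#'   `beta`, `se`, `wald_p`, `fdr`, `pearson_r`, `is_associated`.
#' @export
call_amyloid_genes <- function(glm_results, counts, score, include = NULL,
                               alpha = 0.05, unit = "GM", stain = "AmyloGlo") {
  assert_that(is.numeric(alpha) && alpha > 0 && alpha < 1,
              "alpha must lie in (0, 1)")
  if (is.null(include)) include <- rep(TRUE, ncol(counts))
  norm <- normalize_log1p_cpm(counts[, include, drop = FALSE])
  x <- score[include]
  out <- glm_results
  tested <- !is.na(out$wald_p)
  out$fdr <- NA_real_
  out$fdr[tested] <- stats::p.adjust(out$wald_p[tested], method = "BH")
  out$pearson_r <- vapply(seq_len(nrow(out)), function(g) {
    e <- norm[out$gene[g], ]
    if (stats::sd(e) == 0) return(NA_real_)
    stats::cor(e, x)
  }, numeric(1))
  out$stain <- stain
  out$analysis_unit <- unit
  out$is_associated <- !is.na(out$fdr) & out$fdr < alpha &
    !is.na(out$pearson_r) & out$pearson_r > 0
  out[, c("gene", "stain", "analysis_unit", "beta", "se", "wald_p", "fdr",
          "pearson_r", "is_associated", "reason")]
}

#' Full amyloid-association analysis for one sample set
#'
#' Chains [score_spots()], [build_neighbor_graph()], [gi_star()],
#' [amyloid_glm()] and [call_amyloid_genes()]. In `mode = "human"` the grey
#' matter is pooled and spots of `exclude_regions` (white matter by default)
#' are excluded; in `mode = "mouse"` the analysis runs separately per region
#' label (cluster), skipping units whose score field is constant.
#'
#' @param counts A `counts_table` or genes x spots matrix.
#' @param grid A `spot_grid` aligned to the counts columns.
#' @param binaries An `amyloid_binaries` table (one stain).
#' @param mode `"human"` or `"mouse"`.
#' @param exclude_regions Regions excluded in human mode.
#' @param score_type `"gi_star"` (hotspot field, default) or `"area_z"`
#'   (standardized per-spot total area).
#' @param alpha FDR threshold.
#' @param radius_override Optional effective radius.
#' @return `AmyloidGeneResult` data frame (rows from every analysis unit).
#' @export
run_amyloid_analysis <- function(counts, grid, binaries,
                                 mode = c("human", "mouse"),
                                 exclude_regions = "WM",
                                 score_type = c("gi_star", "area_z"),
                                 alpha = 0.05, radius_override = NULL) {
  mode <- match.arg(mode)
  score_type <- match.arg(score_type)
  mat <- if (inherits(counts, "counts_table")) counts$counts else counts
  assert_that(ncol(mat) == nrow(grid), "counts and grid are misaligned")
  stain <- if (nrow(binaries) > 0) binaries$stain[1] else "AmyloGlo"
  sc <- score_spots(grid, binaries, radius_override)
  score <- if (score_type == "gi_star") {
    graph <- build_neighbor_graph(grid)
    gi_star(sc$total_area_um2, graph)
  } else {
    assert_that(stats::sd(sc$total_area_um2) > 0,
                "constant amyloid area field",
                class = "spotnet_degenerate_field")
    as.numeric(scale(sc$total_area_um2))
  }
  units <- if (mode == "human") {
    list(GM = !(grid$region %in% exclude_regions))
  } else {
    regs <- unique(grid$region)
    stats::setNames(lapply(regs, function(r) grid$region == r), regs)
  }
  res <- list()
  for (u in names(units)) {
    inc <- units[[u]]
    if (sum(inc) < 3 || stats::sd(score[inc]) == 0) next
    glm_res <- amyloid_glm(mat, score, sample = grid$sample_id, include = inc)
    res[[u]] <- call_amyloid_genes(glm_res, mat, score, include = inc,
                                   alpha = alpha, unit = u, stain = stain)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Overlap statistics between two gene sets
#'
#' 2x2 table against a stated background, Jaccard index, one-sided Fisher
#' exact p (enrichment) and the sample odds ratio `(a d)/(b c)` with a
#' Haldane 0.5 continuity correction applied to all cells iff any cell is
#' zero.
#'
#' @param A,B Character vectors, subsets of `background`.
#' @param background Character vector of all eligible genes.
#' @return List with `a`, `b`, `c`, `d`, `jaccard`, `fisher_p`, `odds_ratio`.
#' @export
overlap_gene_sets <- function(A, B, background) {
  assert_that(length(background) > 0, "background must be non-empty")
  assert_that(all(A %in% background) && all(B %in% background),
              "A and B must be subsets of the background")
  A <- unique(A); B <- unique(B); background <- unique(background)
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  cc <- length(setdiff(B, A))
  d <- length(background) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2)
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(a = a, b = b, c = cc, d = d,
       jaccard = if (a + b + cc == 0) NA_real_ else a / (a + b + cc),
       fisher_p = fisher_p,
       odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]))
}
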