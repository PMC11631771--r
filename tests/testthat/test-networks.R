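test_that("prevalence filter keeps a gene at exactly the threshold", {
  counts <- matrix(0L, 3, 80, dimnames = list(c("low", "edge", "high"), NULL))
  groups <- rep(c("A", "B"), each = 40)
  counts["low", 1] <- 1L            # 1/40 = 2.5% in A, 0% in B -> dropped
  counts["edge", 41:42] <- 1L       # 2/40 = 5% in B exactly -> kept
  counts["high", ] <- 3L            # everywhere -> kept
  kept <- filter_expressed_genes(counts, groups)
  expect_false("low" %in% kept)
  expect_true("edge" %in% kept)
  expect_true("high" %in% kept)
  expect_setequal(filter_expressed_genes(counts, groups, min_frac = 0),
                  rownames(counts))
})

test_that("pseudobulk log2-CPM matches hand arithmetic and is scale invariant", {
  counts <- matrix(c(90L, 10L), 2, 1, dimnames = list(c("g1", "g2"), "b1"))
  pb <- pseudobulk_log2cpm(counts, "S1", "L1")
  expect_equal(as.numeric(pb), c(log2(9e5 + 1), log2(1e5 + 1)),
               tolerance = 1e-9)
  expect_equal(as.numeric(pb), c(19.779, 16.610), tolerance = 1e-3)

  # doubling counts leaves CPM unchanged
  pb2 <- pseudobulk_log2cpm(counts * 2L, "S1", "L1")
  expect_equal(as.numeric(pb2), as.numeric(pb))

  # rows sum to 1e6 pre-log
  cfg <- sim_config(seed = 9, n_rows = 8, n_cols = 8)
  g <- make_hex_grid(cfg)
  ct <- simulate_counts(g, simulate_amyloid_binaries(g, cfg, seed = NULL),
                        cfg, seed = NULL)
  pb3 <- pseudobulk_log2cpm(ct$counts, ct$spot_meta$sample_id,
                            ct$spot_meta$region)
  sums <- rowSums(2^pb3 - 1)
  expect_true(all(abs(sums - 1e6) < 1e-6 * 1e6))

  # empty (sample, region) pairs simply produce no row
  expect_equal(nrow(pb3), length(unique(ct$spot_meta$region)))
})

test_that("soft-power selection: scale-free generator passes, noise does not", {
  set.seed(7)
  n <- 400; obs <- 200
  loading <- runif(n)^2
  f <- rnorm(obs)
  x <- sapply(loading, function(a) a * f + sqrt(1 - a^2) * rnorm(obs))
  colnames(x) <- paste0("g", 1:n)
  sp <- suppressWarnings(select_soft_power(x, network_type = "unsigned"))
  expect_true(sp$passed)
  expect_gt(max(sp$fit, na.rm = TRUE), 0.8)
  # chosen power reproduces a direct scan
  pass <- names(sp$fit)[!is.na(sp$fit) & sp$fit > 0.8]
  expect_equal(sp$chosen_power, as.integer(pass[1]))

  noise <- matrix(rnorm(obs * 300), obs, 300,
                  dimnames = list(NULL, paste0("g", 1:300)))
  spn <- suppressWarnings(select_soft_power(noise))
  expect_false(spn$passed)
})

test_that("TOM closed forms and triple-loop oracle", {
  set.seed(2)
  # n = 2: TOM_12 equals the adjacency
  e2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("g1", "g2")))
  a12 <- ((1 + cor(e2)[1, 2]) / 2)^6
  tom2 <- tom_matrix(e2, 6)
  expect_equal(tom2[1, 2], a12, tolerance = 1e-12)
  expect_equal(diag(tom2), c(g1 = 1, g2 = 1))

  # a pair of identical genes has adjacency 1, hence overlap 1
  e3 <- cbind(g1 = e2[, "g1"], g3 = e2[, "g1"])
  tom3 <- tom_matrix(e3, 6)
  expect_equal(tom3["g1", "g3"], 1, tolerance = 1e-12)

  # triple-loop oracle at 10 genes
  e10 <- matrix(rnorm(120), 12, 10, dimnames = list(NULL, paste0("g", 1:10)))
  expect_lt(max(abs(tom_matrix(e10, 6) - brute_tom(e10, 6))), 1e-12)
  expect_lt(max(abs(tom_matrix(e10, 2, "unsigned") -
                      brute_tom(e10, 2, "unsigned"))), 1e-12)

  # constant gene is dropped with a warning
  e4 <- cbind(e2, flat = rep(1, 10))
  expect_warning(t4 <- tom_matrix(e4, 6), "constant")
  expect_equal(ncol(t4), 2)
})

test_that("module detection: planted blocks, min-size rule, eigengene merging", {
  x <- blocks_expr(n_obs = 80, block_size = 60, factor_cor = 0, seed = 11)
  lab <- detect_modules(tom_matrix(x, 12), x, min_module_size = 50)
  expect_equal(length(setdiff(unique(lab), "grey")), 2)
  truth <- rep(c("A", "B"), each = 60)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)

  # a 30-gene block is below min size and stays unassigned while a
  # co-detected 60-gene block is kept
  set.seed(12)
  f1 <- rnorm(80); f2 <- rnorm(80)
  small <- cbind(sapply(1:60, function(i) f1 + 0.3 * rnorm(80)),
                 sapply(1:30, function(i) f2 + 0.3 * rnorm(80)))
  colnames(small) <- paste0("g", 1:90)
  lab_s <- detect_modules(tom_matrix(small, 12), small, min_module_size = 50)
  expect_true(all(lab_s[61:90] == "grey"))
  expect_true(all(lab_s[1:60] == "M1"))

  # blocks whose eigengenes correlate 0.95 merge at merge_height 0.1
  xm <- blocks_expr(n_obs = 80, block_size = 60, factor_cor = 0.95, seed = 11)
  lab_m <- detect_modules(tom_matrix(xm, 12), xm, min_module_size = 50,
                          merge_height = 0.1)
  expect_equal(length(setdiff(unique(lab_m), "grey")), 1)
})

test_that("module eigengenes: rank-1 exactness, equivariance, PCA optimality", {
  set.seed(13)
  base <- rnorm(40)
  expr <- cbind(g1 = base, g2 = 2 * base + 5)
  assign <- c(g1 = "M1", g2 = "M1")
  me <- module_eigengenes(expr, assign)
  expect_equal(abs(cor(me[, "M1"], expr[, "g1"])), 1, tolerance = 1e-12)
  expect_gt(cor(me[, "M1"], expr[, "g1"]), 0)
  expect_equal(sd(me[, "M1"]), 1)

  # permuting observations permutes the eigengene identically
  x <- blocks_expr(n_obs = 50, block_size = 10, seed = 14)
  assign10 <- setNames(rep(c("M1", "M2"), each = 10), colnames(x))
  me1 <- module_eigengenes(x, assign10)
  perm <- sample(50)
  me2 <- module_eigengenes(x[perm, ], assign10)
  expect_equal(unname(me2), unname(me1[perm, ]), ignore_attr = TRUE)

  # first PC beats random unit-norm combinations in summed squared correlation
  z <- scale(x[, 1:10])
  score_of <- function(v) sum(cor(as.numeric(z %*% v), z)^2)
  me_score <- sum(cor(me1[, "M1"], z)^2)
  rand <- replicate(50, {
    v <- rnorm(10); v <- v / sqrt(sum(v^2)); score_of(v)
  })
  expect_true(all(me_score >= rand - 1e-8))

  # all-constant module flagged with zero eigengene
  flat <- matrix(1, 40, 2, dimnames = list(NULL, c("f1", "f2")))
  me3 <- module_eigengenes(flat, c(f1 = "M1", f2 = "M1"))
  expect_true(all(me3 == 0))
  expect_equal(attr(me3, "degenerate"), "M1")
})

test_that("kME is a bounded correlation with exact endpoints", {
  x <- blocks_expr(n_obs = 60, block_size = 10, seed = 15)
  assign10 <- setNames(rep(c("M1", "M2"), each = 10), colnames(x))
  me <- module_eigengenes(x, assign10)
  kme <- module_kme(cbind(x, me1copy = me[, "M1"]), me)
  expect_equal(kme["me1copy", "M1"], 1, tolerance = 1e-12)
  expect_true(all(kme >= -1 - 1e-12 & kme <= 1 + 1e-12))
  set.seed(16)
  indep <- matrix(rnorm(60 * 30), 60, 30, dimnames = list(NULL, paste0("i", 1:30)))
  k0 <- module_kme(indep, me)
  expect_lt(mean(abs(k0)), 0.15)
})

test_that("module projection: self-projection exact, missing modules reported", {
  x <- blocks_expr(n_obs = 70, block_size = 20, seed = 17)
  assign20 <- setNames(rep(c("M1", "M2"), each = 20), colnames(x))
  me <- module_eigengenes(x, assign20)
  proj <- project_modules(assign20, x)
  expect_gt(abs(cor(proj[, "M1"], me[, "M1"])), 0.999)
  expect_gt(abs(cor(proj[, "M2"], me[, "M2"])), 0.999)

  # half the genes missing still tracks the latent factor
  set.seed(18)
  keep_genes <- c(sample(colnames(x)[1:20], 10), colnames(x)[21:40])
  proj2 <- project_modules(assign20, x[, keep_genes])
  expect_gt(abs(cor(proj2[, "M1"], me[, "M1"])), 0.8)

  # a module entirely absent is skipped and listed
  proj3 <- project_modules(assign20, x[, 21:40])
  expect_equal(attr(proj3, "skipped"), "M1")
  expect_equal(colnames(proj3), "M2")
})

test_that("meta-spots conserve UMI and bin the lattice", {
  cfg <- sim_config(seed = 19, n_rows = 4, n_cols = 4, region_layout = c("A", "B"))
  g <- make_hex_grid(cfg)
  ct <- simulate_counts(g, simulate_amyloid_binaries(g, cfg, seed = NULL),
                        cfg, seed = NULL)
  ms <- make_metaspots(g, ct$counts, bin_width_spots = 2)
  expect_equal(nrow(ms$grid), 4)
  expect_true(all(table(paste(g$array_row %/% 2, g$array_col %/% 2)) == 4))
  expect_equal(sum(ms$counts), sum(ct$counts))
  expect_equal(rowSums(ms$counts), rowSums(ct$counts))

  ms1 <- make_metaspots(g, ct$counts, bin_width_spots = 1)
  expect_equal(nrow(ms1$grid), nrow(g))
  expect_equal(sum(ms1$counts), sum(ct$counts))
})

test_that("consensus TOM: identity, element-wise minimum, symmetry", {
  set.seed(20)
  e1 <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  e2 <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  t1 <- tom_matrix(e1, 6); t2 <- tom_matrix(e2, 6)
  same <- consensus_tom(list(t1, t1))
  expect_equal(same, t1, tolerance = 1e-12)
  cons <- consensus_tom(list(t1, t2))
  expect_true(isSymmetric(cons))
  q <- quantile(t1[upper.tri(t1)], 0.95) / quantile(t2[upper.tri(t2)], 0.95)
  off <- upper.tri(cons)
  expect_true(all(cons[off] <= t1[off] + 1e-12))
  expect_true(all(cons[off] <= (t2 * q)[off] + 1e-12))
  expect_warning(consensus_tom(list(t1)), "passthrough")
})
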