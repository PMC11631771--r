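test_that("pairwise Jaccard: arithmetic, identity, disjointness", {
  mg <- list("L1-M1" = c("g1", "g2", "g3"),
             "L2/3-M1" = c("g2", "g3", "g4"),
             "L2/3-M2" = c("g9", "g10"),
             "WM-M1" = c("g1", "g2", "g3"))
  J <- pairwise_jaccard(mg)
  expect_equal(J["L1-M1", "L2/3-M1"], 0.5)
  expect_equal(J["L1-M1", "WM-M1"], 1)
  expect_equal(J["L1-M1", "L2/3-M2"], 0)
  expect_true(isSymmetric(J))
  expect_equal(diag(J), setNames(rep(1, 4), names(mg)))
  expect_error(pairwise_jaccard(list("L1-M1" = "g1",
                                     "L1-M2" = character())), "empty")
  # within-region overlap violates the partition and is caught
  expect_error(pairwise_jaccard(list("L1-M1" = c("g1", "g2"),
                                     "L1-M2" = c("g2", "g3"))), "partition")
})

test_that("E takes the component-wise maximum over regions", {
  set.seed(30)
  n <- 90
  regions <- rep(c("R1", "R2", "R3"), each = 30)
  f <- rnorm(n)
  m1 <- f
  # correlated +0.9-ish in R1 and -0.9-ish in R2 by construction
  m2 <- c(f[1:30], -f[31:60], rnorm(30))
  me <- cbind(A = m1, B = m2)
  E <- max_cross_correlation(me, regions)
  expect_equal(E["A", "B"], 1, tolerance = 1e-9) # exact copy within R1
  expect_true(isSymmetric(E))

  # identical MEs everywhere
  me2 <- cbind(A = m1, B = m1)
  expect_equal(max_cross_correlation(me2, regions)["A", "B"], 1)

  # brute-force per-region scan oracle
  set.seed(31)
  me3 <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("M", 1:5)))
  E3 <- max_cross_correlation(me3, regions)
  brute <- matrix(-Inf, 5, 5)
  for (r in unique(regions)) {
    brute <- pmax(brute, cor(me3[regions == r, ]))
  }
  diag(brute) <- 1
  expect_equal(unname(E3), unname(brute), tolerance = 1e-12)
})

test_that("meta-dissimilarity forced values and bounds", {
  E <- matrix(c(1, 1, 1, 1), 2, 2)
  J <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(meta_dissimilarity(E, J), matrix(0, 2, 2))
  expect_equal(meta_dissimilarity(E * 0, J * 0), matrix(1, 2, 2))
  expect_equal(meta_dissimilarity(E * 0 + 0.5, J * 0 + 0.3)[1, 1], 0.65)
  # literal parenthesization goes negative at E = J = 1
  expect_equal(meta_dissimilarity(E, J, literal = TRUE)[1, 1], -0.75)

  set.seed(32)
  Er <- matrix(runif(49, -1, 1), 7, 7); Er <- (Er + t(Er)) / 2; diag(Er) <- 1
  Jr <- matrix(runif(49), 7, 7); Jr <- (Jr + t(Jr)) / 2; diag(Jr) <- 1
  D <- meta_dissimilarity(Er, Jr)
  expect_true(isSymmetric(D))
  expect_true(all(D >= 0 - 1e-12 & D <= 1.25 + 1e-12))
  expect_true(all(D[Er >= 0] <= 1 + 1e-12))
})

test_that("meta-module clustering: singletons, invariance, family recovery", {
  des <- family_design(seed = 21)
  J <- pairwise_jaccard(des$module_genes)
  E <- max_cross_correlation(des$me, des$regions)
  D <- meta_dissimilarity(E, J)

  singletons <- cluster_metamodules(D, k = nrow(D))
  expect_equal(length(unique(singletons$map)), nrow(D))
  expect_error(cluster_metamodules(D, k = nrow(D) + 1), "between")

  cm <- cluster_metamodules(D, k = 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cm$map, des$family), 1)

  # permuting module order permutes, not changes, the partition
  perm <- sample(nrow(D))
  cm2 <- cluster_metamodules(D[perm, perm], k = 2)
  expect_equal(mclust::adjustedRandIndex(cm2$map[rownames(D)], cm$map), 1)
})

test_that("gene re-assignment follows maximal kME with lexicographic ties", {
  mg <- list("L1-M1" = c("g1", "g2", "shared"),
             "WM-M1" = c("g3", "g4", "shared"))
  meta_map <- c("L1-M1" = "meta-M1", "WM-M1" = "meta-M2")
  kme <- matrix(c(0.8, 0.3), 1, 2,
                dimnames = list("shared", c("meta-M1", "meta-M2")))
  out <- assign_genes_to_metamodules(mg, meta_map, kme)
  expect_equal(unname(out["g1"]), "meta-M1")   # single module: inherited
  expect_equal(unname(out["g3"]), "meta-M2")
  expect_equal(unname(out["shared"]), "meta-M1") # 0.8 beats 0.3

  kme_tie <- matrix(c(0.5, 0.5), 1, 2,
                    dimnames = list("shared", c("meta-M1", "meta-M2")))
  out_tie <- assign_genes_to_metamodules(mg, meta_map, kme_tie)
  expect_equal(unname(out_tie["shared"]), "meta-M1")

  kme_na <- matrix(NA_real_, 1, 2,
                   dimnames = list("shared", c("meta-M1", "meta-M2")))
  out_na <- assign_genes_to_metamodules(mg, meta_map, kme_na)
  expect_equal(unname(out_na["shared"]), "unassigned")
  expect_equal(attr(out_na, "unassigned"), "shared")
})

test_that("re-assignment is optimal: no gene beats its meta-module kME elsewhere", {
  des <- family_design(seed = 33)
  # contaminate: 15 genes shared between modules of different families, so
  # they end up claimed by both meta-modules
  shared <- des$module_genes[["R1-M1"]][1:15]
  des$module_genes[["R2-M2"]] <- c(des$module_genes[["R2-M2"]][-(1:15)],
                                   shared)
  # keep the within-region partition intact
  des$module_genes[["R2-M1"]] <- setdiff(des$module_genes[["R2-M1"]], shared)
  cm <- cluster_metamodules(
    meta_dissimilarity(max_cross_correlation(des$me, des$regions),
                       pairwise_jaccard(des$module_genes)), k = 2)
  # expression that carries the family factors so kME is meaningful
  set.seed(34)
  expr <- matrix(rnorm(300 * 600, sd = 0.5), 300, 600,
                 dimnames = list(NULL, paste0("g", 1:600)))
  for (m in names(des$module_genes)) {
    expr[, des$module_genes[[m]]] <- expr[, des$module_genes[[m]]] +
      des$me[, m]
  }
  meta_me <- metamodule_eigengenes(expr, des$module_genes, cm$map)
  kme <- module_kme(expr, meta_me)
  out <- assign_genes_to_metamodules(des$module_genes, cm$map, kme)
  multi <- names(out)[sapply(names(out), function(g) {
    length(unique(cm$map[sapply(des$module_genes, function(s) g %in% s)])) > 1
  })]
  expect_gte(length(multi), 15)
  for (g in multi[out[multi] != "unassigned"]) {
    claimed <- unique(cm$map[sapply(des$module_genes, function(s) g %in% s)])
    expect_equal(kme[g, out[g]], max(kme[g, claimed], na.rm = TRUE))
  }
})

test_that("DME test: exact separation p, identical groups, home-region rule", {
  me <- matrix(c(1:10, 21:30), 20, 1, dimnames = list(NULL, "L1-M1"))
  group <- rep(c("ctl", "dis"), each = 10)
  res <- dme_test(me, group, contrast = c("dis", "ctl"))
  # complete separation: exact two-sided rank-sum tail
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$effect, 20)

  me_same <- matrix(rep(1:10, 2), 20, 1, dimnames = list(NULL, "M"))
  res_same <- dme_test(me_same, group, contrast = c("dis", "ctl"))
  expect_equal(res_same$effect, 0)
  expect_equal(res_same$p, 1)

  # region-specific module tested only at home; meta-module everywhere
  set.seed(35)
  n <- 60
  regions <- rep(c("L1", "WM"), each = 30)
  grp <- rep(rep(c("ctl", "dis"), each = 15), 2)
  me2 <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("L1-M1", "meta-M1")))
  res2 <- dme_test(me2, grp, c("dis", "ctl"), regions = regions,
                   module_home = c("L1-M1" = "L1"))
  expect_equal(res2$region[res2$module == "L1-M1"], "L1")
  expect_setequal(res2$region[res2$module == "meta-M1"], c("L1", "WM"))
  expect_true(all(res2$fdr >= res2$p - 1e-12))
})

test_that("DME p values are uniform under a permuted null", {
  set.seed(36)
  me <- matrix(rnorm(40 * 100), 40, 100,
               dimnames = list(NULL, paste0("M", 1:100)))
  group <- sample(rep(c("a", "b"), each = 20))
  res <- dme_test(me, group, c("a", "b"))
  # rank-sum p values are discrete, so check uniformity coarsely
  expect_lt(abs(mean(res$p < 0.25) - 0.25), 0.15)
  expect_gt(mean(res$p), 0.35)
  expect_lt(mean(res$p), 0.65)
})

test_that("score correlations: exact self, near-zero independent, small groups skipped", {
  set.seed(37)
  me <- matrix(rnorm(50 * 2), 50, 2, dimnames = list(NULL, c("M1", "M2")))
  res <- correlate_scores(me, me[, "M1"])
  expect_equal(res$r[res$module == "M1"], 1, tolerance = 1e-12)

  indep <- rnorm(50)
  res2 <- correlate_scores(me, indep)
  expect_lt(max(abs(res2$r)), 0.35)

  groupby <- c(rep("big", 48), "tiny", "tiny")
  res3 <- correlate_scores(me, indep, groupby)
  expect_false("tiny" %in% res3$group)
})

test_that("meta-module stage is deterministic on identical inputs", {
  des <- family_design(seed = 38)
  run <- function() {
    J <- pairwise_jaccard(des$module_genes)
    E <- max_cross_correlation(des$me, des$regions)
    cluster_metamodules(meta_dissimilarity(E, J), k = 3)$map
  }
  expect_identical(run(), run())
})
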