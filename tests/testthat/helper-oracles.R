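# Independent oracles, coded directly from the defining formulas.
# These stay deliberately naive (loops, enumeration) so they cannot share a
# bug with the vectorized implementations they check.

# Getis-Ord Gi* by direct summation over the weight matrix
brute_gi_star <- function(x, adj) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  sapply(seq_len(n), function(i) {
    w <- as.numeric(adj[i, ])
    w[i] <- 1
    W <- sum(w)
    (sum(w * x) - xbar * W) / (S * sqrt((n * sum(w^2) - W^2) / (n - 1)))
  })
}

# topological overlap by triple loop
brute_tom <- function(expr, power, type = "signed") {
  cc <- cor(expr)
  a <- if (type == "signed") ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 0
  p <- ncol(a)
  k <- colSums(a)
  tom <- matrix(1, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      num <- a[i, j]
      for (u in seq_len(p)) {
        if (u != i && u != j) num <- num + a[i, u] * a[u, j]
      }
      tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# one-sided (enrichment) hypergeometric tail by explicit summation
brute_hyper_p <- function(a, nA, nB, N) {
  hi <- min(nA, nB)
  sum(sapply(a:hi, function(i) {
    choose(nA, i) * choose(N - nA, nB - i) / choose(N, nB)
  }))
}

# two planted expression blocks driven by latent factors with a given
# factor correlation
blocks_expr <- function(n_obs = 80, block_size = 60, factor_cor = 0,
                        noise_sd = 0.3, seed = 11) {
  set.seed(seed)
  f1 <- rnorm(n_obs)
  f2 <- factor_cor * f1 + sqrt(1 - factor_cor^2) * rnorm(n_obs)
  x <- cbind(
    sapply(seq_len(block_size), function(i) f1 + noise_sd * rnorm(n_obs)),
    sapply(seq_len(block_size), function(i) f2 + noise_sd * rnorm(n_obs))
  )
  colnames(x) <- paste0("g", seq_len(2 * block_size))
  x
}

# 12-module / 2-family / 3-region meta-module design with planted families
family_design <- function(seed = 21) {
  set.seed(seed)
  n_spots <- 300
  regions <- rep(c("R1", "R2", "R3"), each = 100)
  fa <- rnorm(n_spots)
  fb <- rnorm(n_spots)
  me <- sapply(1:12, function(m) {
    f <- if (m %% 2 == 1) fa else fb
    f + 0.4 * rnorm(n_spots)
  })
  colnames(me) <- paste0(rep(c("R1", "R2", "R3"), each = 4), "-M", rep(1:4, 3))
  genes_all <- paste0("g", 1:600)
  module_genes <- list()
  for (r in 1:3) {
    for (k in 1:4) {
      fam <- if (k %% 2 == 1) 1 else 2
      pool <- if (fam == 1) genes_all[1:300] else genes_all[301:600]
      idx <- ((k + 1) %/% 2 - 1) * 100
      module_genes[[paste0("R", r, "-M", k)]] <-
        pool[(idx + 1):(idx + 100)][sample(100, 60)]
    }
  }
  list(me = me, regions = regions,
       module_genes = module_genes[colnames(me)],
       family = rep(rep(c("A", "B"), 2), 3))
}

# shared 12-sample default synthetic study, built once per test run
cached_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(seed = 1), n_samples = 12)
    }
    cache
  }
})

study_pseudobulk <- function(study) {
  allc <- do.call(cbind, lapply(study$counts, function(ct) ct$counts))
  samp <- unlist(lapply(study$counts, function(ct) ct$spot_meta$sample_id))
  reg <- unlist(lapply(study$counts, function(ct) ct$spot_meta$region))
  keep <- filter_expressed_genes(allc, reg)
  list(pb = pseudobulk_log2cpm(allc[keep, , drop = FALSE], samp, reg),
       counts = allc, sample = samp, region = reg, genes = keep)
}
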