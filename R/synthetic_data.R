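#' Simulation configuration for synthetic spatial-transcriptomics studies
#'
#' Bundles every parameter of the synthetic-data generator: the hexagonal
#' lattice geometry, the negative-binomial count model with region-restricted
#' co-expression modules and amyloid-responsive genes, the clustered amyloid
#' point process, and the cortical region layout.
#'
#' The count model for spot \eqn{s} and gene \eqn{g} is
#' \deqn{\mu_{gs} = L_s \exp(\alpha_g + \sum_m \lambda_{gm} f_{ms} + \beta_g a_s)}
#' where \eqn{L_s} is a log-normal library-size factor, \eqn{f_{ms}} a latent
#' factor drawn once per (module, sample) and shared by spots of the module's
#' home region (zero elsewhere), \eqn{\lambda_{gm} = 1} for genes of module
#' \eqn{m}, \eqn{a_s} the standardized per-spot total amyloid area (computed
#' with the same spot-binary intersection rule the analysis uses), and
#' \eqn{\beta_g} the planted amyloid coefficient. Counts are negative binomial
#' with size `nb_dispersion`.
#'
#' Defaults describe the reference synthetic study: a 20x20 lattice with
#' 100 um pitch and 55 um spots, seven cortical row bands (L1..WM), 200 genes
#' of baseline mean count ~5, two planted 60-gene modules, and 20
#' amyloid-responsive genes with log-linear coefficient 0.5.
#'
#' @param seed Integer seed for the generator's random stream.
#' @param n_rows,n_cols Lattice dimensions (rows x columns of spots).
#' @param spacing_um Center-to-center spot distance in micrometers.
#' @param diameter_um Spot diameter in micrometers; must be < `spacing_um`.
#' @param n_genes Number of simulated genes.
#' @param n_modules,module_size Number and size of planted co-expression
#'   modules; module genes occupy the first `n_modules * module_size` gene
#'   slots. `module_size >= 2`.
#' @param factor_sd Standard deviation of the per-(module, sample) latent
#'   factor.
#' @param alpha_logmean,alpha_logsd Per-gene baseline log-intensity
#'   \eqn{\alpha_g \sim N(}`alpha_logmean`, `alpha_logsd`\eqn{)}.
#' @param nb_dispersion Negative-binomial size parameter (> 0).
#' @param libsize_logmean,libsize_logsd Log-normal parameters of the per-spot
#'   library-size factor.
#' @param amyloid_beta Numeric vector of length `n_genes` of true log-linear
#'   amyloid coefficients (0 for null genes), or `NULL` for the default of
#'   0.5 on the last `min(20, n_genes)` genes.
#' @param n_amyloid_centers,binaries_per_center Number of amyloid cluster
#'   centers and of binaries per center.
#' @param center_spread_um Isotropic Gaussian displacement sd of binaries
#'   around their center, micrometers.
#' @param area_logmean,area_logsd Log-normal parameters of binary areas (um^2).
#' @param region_layout Ordered character vector of region labels assigned to
#'   contiguous lattice row bands, top to bottom.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [make_hex_grid()], [simulate_counts()], [simulate_study()]
#' @export
sim_config <- function(seed = 1L,
                       n_rows = 20L, n_cols = 20L,
                       spacing_um = 100, diameter_um = 55,
                       n_genes = 200L, n_modules = 2L, module_size = 60L,
                       factor_sd = 1,
                       alpha_logmean = log(5), alpha_logsd = 0.25,
                       nb_dispersion = 2,
                       libsize_logmean = 0, libsize_logsd = 0.2,
                       amyloid_beta = NULL,
                       n_amyloid_centers = 10L, binaries_per_center = 30L,
                       center_spread_um = 150,
                       area_logmean = log(200), area_logsd = 0.5,
                       region_layout = c("L1", "L2/3", "L3/4", "L3-L5",
                                         "L5/6", "L6b", "WM")) {
  assert_that(is_count(seed), "seed must be a single integer")
  assert_that(is_count(n_rows) && n_rows >= 1 && is_count(n_cols) && n_cols >= 1,
              "n_rows and n_cols must be positive integers")
  assert_that(is.numeric(spacing_um) && is.numeric(diameter_um) &&
                spacing_um > diameter_um && diameter_um > 0,
              "need spacing_um > diameter_um > 0")
  assert_that(is_count(n_genes) && n_genes >= 1, "n_genes must be >= 1")
  assert_that(is_count(n_modules) && n_modules >= 0, "n_modules must be >= 0")
  assert_that(is_count(module_size) && module_size >= 2,
              "module_size must be an integer >= 2")
  assert_that(n_modules * module_size <= n_genes,
              "planted modules need n_modules * module_size <= n_genes")
  assert_that(is.numeric(nb_dispersion) && is.finite(nb_dispersion) &&
                nb_dispersion > 0, "nb_dispersion must be > 0")
  for (nm in c("factor_sd", "alpha_logmean", "alpha_logsd", "libsize_logmean",
               "libsize_logsd", "center_spread_um", "area_logmean",
               "area_logsd")) {
    v <- get(nm)
    assert_that(is.numeric(v) && length(v) == 1L && is.finite(v),
                "%s must be a finite number", nm)
  }
  if (is.null(amyloid_beta)) {
    amyloid_beta <- numeric(n_genes)
    n_hit <- min(20L, n_genes)
    if (n_hit > 0) amyloid_beta[(n_genes - n_hit + 1L):n_genes] <- 0.5
  }
  assert_that(length(amyloid_beta) == n_genes && all(is.finite(amyloid_beta)),
              "amyloid_beta must be a finite vector of length n_genes")
  assert_that(is_count(n_amyloid_centers) && n_amyloid_centers >= 0,
              "n_amyloid_centers must be >= 0")
  assert_that(is_count(binaries_per_center) && binaries_per_center >= 1,
              "binaries_per_center must be >= 1")
  assert_that(is.character(region_layout) && length(region_layout) >= 1 &&
                !anyDuplicated(region_layout),
              "region_layout must be distinct region labels")
  structure(list(
    seed = as.integer(seed),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    spacing_um = spacing_um, diameter_um = diameter_um,
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), factor_sd = factor_sd,
    alpha_logmean = alpha_logmean, alpha_logsd = alpha_logsd,
    nb_dispersion = nb_dispersion,
    libsize_logmean = libsize_logmean, libsize_logsd = libsize_logsd,
    amyloid_beta = amyloid_beta,
    n_amyloid_centers = as.integer(n_amyloid_centers),
    binaries_per_center = as.integer(binaries_per_center),
    center_spread_um = center_spread_um,
    area_logmean = area_logmean, area_logsd = area_logsd,
    region_layout = region_layout
  ), class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key-value YAML; keys are the arguments of [sim_config()]. Unknown keys
#' are an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  assert_that(length(bad) == 0, "unknown config keys: %s",
              paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

#' Build a hexagonal Visium-style spot lattice
#'
#' Constructs a triangular lattice: odd array rows are offset by half the
#' pitch in x and row spacing is `spacing_um * sqrt(3)/2`, so that all
#' nearest-neighbour center distances equal `spacing_um`. Region labels from
#' `config$region_layout` are assigned to contiguous row bands, top band
#' first.
#'
#' @param config A [sim_config()] object.
#' @param sample_id Sample identifier stored on every spot.
#' @return A `spot_grid`: a data frame with columns `barcode`, `array_row`,
#'   `array_col`, `x_um`, `y_um`, `region`, `sample_id`, and attributes
#'   `spacing_um` and `diameter_um`.
#' @export
make_hex_grid <- function(config, sample_id = "S1") {
  stopifnot(inherits(config, "sim_config"))
  nr <- config$n_rows; nc <- config$n_cols
  assert_that(nr >= 1 && nc >= 1, "lattice dimensions must be positive")
  row <- rep(seq_len(nr) - 1L, each = nc)
  col <- rep(seq_len(nc) - 1L, times = nr)
  x <- col * config$spacing_um + (row %% 2L) * config$spacing_um / 2
  y <- row * config$spacing_um * sqrt(3) / 2
  n_reg <- length(config$region_layout)
  band <- ceiling((row + 1L) * n_reg / nr)
  band[band > n_reg] <- n_reg
  grid <- data.frame(
    barcode = sprintf("%s_spot%05d", sample_id, seq_along(row)),
    array_row = row, array_col = col,
    x_um = x, y_um = y,
    region = config$region_layout[band],
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  attr(grid, "spacing_um") <- config$spacing_um
  attr(grid, "diameter_um") <- config$diameter_um
  class(grid) <- c("spot_grid", "data.frame")
  grid
}

#' Simulate clustered amyloid binaries over a spot grid
#'
#' Draws `n_amyloid_centers` cluster centers uniformly over the grid bounding
#' box, then `binaries_per_center` binaries per center with isotropic Gaussian
#' displacement (`center_spread_um`). Areas are log-normal and
#' `diameter = 2 sqrt(area / pi)`.
#'
#' @param grid A `spot_grid`.
#' @param config A [sim_config()] object.
#' @param stain Stain label for the whole table, `"AmyloGlo"` or `"OC"`.
#' @param seed Integer seed, or `NULL` to draw from the current random
#'   stream.
#' @return An `amyloid_binaries` data frame with columns `stain`, `x_um`,
#'   `y_um`, `area_um2`, `diameter_um`, `sample_id`, `center_id` (generating
#'   center, part of the ground truth).
#' @export
simulate_amyloid_binaries <- function(grid, config,
                                      stain = c("AmyloGlo", "OC"),
                                      seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(nrow(grid) >= 1, "grid must be non-empty")
  stain <- match.arg(stain)
  if (!is.null(seed)) set.seed(seed)
  k <- config$n_amyloid_centers
  if (k == 0L) {
    out <- data.frame(stain = character(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), diameter_um = numeric(),
                      sample_id = character(), center_id = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("amyloid_binaries", "data.frame")
    return(out)
  }
  cx <- stats::runif(k, min(grid$x_um), max(grid$x_um))
  cy <- stats::runif(k, min(grid$y_um), max(grid$y_um))
  b <- config$binaries_per_center
  center_id <- rep(seq_len(k), each = b)
  x <- cx[center_id] + stats::rnorm(k * b, 0, config$center_spread_um)
  y <- cy[center_id] + stats::rnorm(k * b, 0, config$center_spread_um)
  area <- stats::rlnorm(k * b, config$area_logmean, config$area_logsd)
  out <- data.frame(
    stain = stain, x_um = x, y_um = y, area_um2 = area,
    diameter_um = 2 * sqrt(area / pi),
    sample_id = grid$sample_id[1L], center_id = center_id,
    stringsAsFactors = FALSE
  )
  attr(out, "centers") <- data.frame(center_id = seq_len(k), x_um = cx, y_um = cy)
  class(out) <- c("amyloid_binaries", "data.frame")
  out
}

# planted gene -> module map implied by a config; "none" for unassigned genes
planted_modules <- function(config) {
  mod <- rep("none", config$n_genes)
  if (config$n_modules > 0) {
    idx <- seq_len(config$n_modules * config$module_size)
    mod[idx] <- paste0("M", rep(seq_len(config$n_modules),
                                each = config$module_size))
  }
  names(mod) <- sprintf("gene%04d", seq_len(config$n_genes))
  mod
}

# home region per planted module, round-robin over the region layout
module_home_regions <- function(config) {
  if (config$n_modules == 0) return(character())
  regs <- config$region_layout
  stats::setNames(regs[((seq_len(config$n_modules) - 1L) %% length(regs)) + 1L],
                  paste0("M", seq_len(config$n_modules)))
}

#' Simulate spot-level UMI counts with planted structure
#'
#' Implements the count model documented in [sim_config()]: log-normal
#' library sizes, per-(module, sample) latent factors restricted to each
#' module's home region, and a log-linear amyloid effect on the standardized
#' per-spot total amyloid area (computed with [score_spots()], the same
#' intersection rule the analysis uses).
#'
#' @param grid A `spot_grid` (one sample).
#' @param binaries An `amyloid_binaries` table for the same sample (may be
#'   empty; the amyloid score is then identically zero).
#' @param config A [sim_config()] object.
#' @param seed Integer seed, or `NULL` to draw from the current stream.
#' @return A `counts_table`: list with `counts` (genes x spots integer
#'   matrix, dimnames set), `spot_meta` (barcode, sample_id, total_umi,
#'   region, amyloid_score), `sample_meta` (one row: sample_id, diagnosis,
#'   sex, pmi, rin, batch), and `truth` (gene -> module map, gene ->
#'   amyloid_beta map, latent factors).
#' @export
simulate_counts <- function(grid, binaries, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(grid, "spot_grid"))
  if (!is.null(seed)) set.seed(seed)
  n_spots <- nrow(grid)
  n_genes <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(n_genes))

  alpha <- stats::rnorm(n_genes, config$alpha_logmean, config$alpha_logsd)
  L <- stats::rlnorm(n_spots, config$libsize_logmean, config$libsize_logsd)

  # standardized per-spot total amyloid area, same rule as the analysis
  if (nrow(binaries) > 0) {
    sc <- score_spots(grid, binaries)
    a <- sc$total_area_um2
    a <- if (stats::sd(a) > 0) as.numeric(scale(a)) else numeric(n_spots)
  } else {
    a <- numeric(n_spots)
  }

  mod <- planted_modules(config)
  homes <- module_home_regions(config)
  eta <- matrix(alpha, n_genes, n_spots) # log-intensity before library size
  fdraw <- stats::setNames(numeric(config$n_modules),
                           sprintf("M%d", seq_len(config$n_modules)))
  if (config$n_modules > 0) {
    for (m in names(homes)) {
      f <- stats::rnorm(1, 0, config$factor_sd)
      fdraw[m] <- f
      in_home <- grid$region == homes[[m]]
      gidx <- which(mod == m)
      if (any(in_home)) eta[gidx, in_home] <- eta[gidx, in_home] + f
    }
  }
  eta <- eta + outer(config$amyloid_beta, a)
  mu <- sweep(exp(eta), 2L, L, `*`)
  counts <- matrix(
    stats::rnbinom(n_genes * n_spots, size = config$nb_dispersion, mu = mu),
    n_genes, n_spots, dimnames = list(genes, grid$barcode)
  )
  spot_meta <- data.frame(
    barcode = grid$barcode, sample_id = grid$sample_id,
    total_umi = colSums(counts), region = grid$region,
    amyloid_score = a, libsize_factor = L, stringsAsFactors = FALSE
  )
  sample_meta <- data.frame(
    sample_id = grid$sample_id[1L], diagnosis = "control", sex = "F",
    pmi = 6, rin = 7, batch = "b1", stringsAsFactors = FALSE
  )
  structure(list(
    counts = counts, spot_meta = spot_meta, sample_meta = sample_meta,
    truth = list(gene_module = mod,
                 amyloid_beta = stats::setNames(config$amyloid_beta, genes),
                 module_home = homes, factors = fdraw)
  ), class = "counts_table")
}

#' Simulate a multi-sample synthetic study
#'
#' Generates `n_samples` samples from one configuration with a shared gene ->
#' module ground truth and independent per-sample latent factors, library
#' sizes and amyloid point processes. The single random stream is seeded once
#' from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param n_samples Number of samples.
#' @param diagnosis Optional character vector of per-sample diagnoses
#'   (recycled); default alternates `"control"` / `"DSAD"`.
#' @return List with `grids`, `counts` (lists per sample), `binaries`, and
#'   `truth` (shared gene -> module and gene -> beta maps).
#' @export
simulate_study <- function(config, n_samples = 12L, diagnosis = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(is_count(n_samples) && n_samples >= 1,
              "n_samples must be a positive integer")
  if (is.null(diagnosis)) {
    diagnosis <- rep(c("control", "DSAD"), length.out = n_samples)
  } else {
    diagnosis <- rep(diagnosis, length.out = n_samples)
  }
  set.seed(config$seed)
  ids <- sprintf("S%02d", seq_len(n_samples))
  grids <- list(); counts <- list(); binaries <- list()
  for (i in seq_len(n_samples)) {
    g <- make_hex_grid(config, sample_id = ids[i])
    b <- simulate_amyloid_binaries(g, config, seed = NULL)
    ct <- simulate_counts(g, b, config, seed = NULL)
    ct$sample_meta$diagnosis <- diagnosis[i]
    ct$sample_meta$sex <- if (i %% 2L) "F" else "M"
    grids[[ids[i]]] <- g
    counts[[ids[i]]] <- ct
    binaries[[ids[i]]] <- b
  }
  list(grids = grids, counts = counts, binaries = binaries,
       truth = list(gene_module = planted_modules(config),
                    amyloid_beta = stats::setNames(
                      config$amyloid_beta, sprintf("gene%04d", seq_len(config$n_genes))),
                    module_home = module_home_regions(config),
                    diagnosis = stats::setNames(diagnosis, ids)))
}

#' Simulate noisy multi-sample cell-to-region mappings
#'
#' One row per (cell, mapping sample). The assigned label equals the true
#' region with probability `1 - flip_prob`, otherwise uniform over the other
#' regions.
#'
#' @param true_regions Named character vector, cell id -> true region.
#' @param n_samples Number of mapping samples.
#' @param flip_prob Probability in `[0, 1]` of mislabeling.
#' @param seed Integer seed.
#' @return A `cell_mappings` data frame: `cell_id`, `st_sample_id`,
#'   `region_label`.
#' @export
simulate_cell_mappings <- function(true_regions, n_samples, flip_prob, seed = 1L) {
  assert_that(is.character(true_regions) && !is.null(names(true_regions)),
              "true_regions must be a named character vector")
  assert_that(is.numeric(flip_prob) && flip_prob >= 0 && flip_prob <= 1,
              "flip_prob must lie in [0, 1]")
  assert_that(is_count(n_samples) && n_samples >= 1,
              "n_samples must be a positive integer")
  set.seed(seed)
  regions <- sort(unique(unname(true_regions)))
  cells <- names(true_regions)
  n <- length(cells)
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    lab <- unname(true_regions)
    flip <- stats::runif(n) < flip_prob
    if (any(flip) && length(regions) > 1) {
      lab[flip] <- vapply(lab[flip], function(r) {
        others <- setdiff(regions, r)
        others[sample.int(length(others), 1L)]
      }, character(1))
    }
    out[[s]] <- data.frame(cell_id = cells,
                           st_sample_id = sprintf("S%02d", s),
                           region_label = lab, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cell_mappings", "data.frame")
  res
}

#' Write a complete synthetic fixture set to a directory
#'
#' Writes the positions CSV, MatrixMarket counts with gene/barcode sidecars,
#' binaries CSV and ground-truth TSVs for each sample of a simulated study.
#' All output is plain text; a fixed `config$seed` makes the output
#' byte-identical across runs.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()] object.
#' @param n_samples Number of samples to simulate.
#' @return Invisibly, the list returned by [simulate_study()].
#' @export
write_fixture_set <- function(dir, config, n_samples = 2L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config, n_samples = n_samples)
  for (id in names(study$grids)) {
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    write_tissue_positions(study$grids[[id]], file.path(sdir, "positions.csv"))
    write_counts_mtx(study$counts[[id]], sdir)
    write_binaries_csv(study$binaries[[id]], file.path(sdir, "binaries.csv"))
  }
  truth <- data.frame(gene = names(study$truth$gene_module),
                      module = unname(study$truth$gene_module),
                      amyloid_beta = unname(study$truth$amyloid_beta))
  utils::write.table(truth, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(study)
}
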