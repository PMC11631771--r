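#' Label mapped cells by their k nearest spots
#'
#' For each predicted cell position, the Euclidean distances to all spots of
#' the sample are computed and the cell is labelled with the most frequent
#' region among the `k` nearest spots. Distance ties at the k-th neighbour
#' break by spot order in the grid; mode ties break to the lexicographically
#' smallest region.
#'
#' @param cells Data frame with `cell_id`, `x_um`, `y_um` (predicted
#'   coordinates in one sample).
#' @param grid A `spot_grid` for the same sample.
#' @param k Number of neighbours (reduced with a warning if the grid has
#'   fewer spots).
#' @return Data frame: `cell_id`, `region_label`.
#' @export
assign_regions_knn <- function(cells, grid, k = 10) {
  assert_that(nrow(grid) >= 1, "grid must be non-empty")
  if (nrow(grid) < k) {
    warnf("grid has %d spots < k = %d; using all spots", nrow(grid), k)
    k <- nrow(grid)
  }
  lab <- vapply(seq_len(nrow(cells)), function(i) {
    d <- sqrt((grid$x_um - cells$x_um[i])^2 + (grid$y_um - cells$y_um[i])^2)
    nn <- order(d, seq_along(d))[seq_len(k)] # spot order breaks distance ties
    lex_mode(grid$region[nn])
  }, character(1))
  data.frame(cell_id = cells$cell_id, region_label = lab,
             stringsAsFactors = FALSE)
}

#' Grey-/white-matter composition metric of a sample
#'
#' `(n_GM - n_WM) / n_total`: positive values indicate grey-matter-rich
#' sections, negative values white-matter-rich sections. The denominator is
#' all spots, including regions in neither set.
#'
#' @param grid A `spot_grid`.
#' @param gm_labels,wm_labels Region labels counted as grey and white matter.
#' @return List: `sample_id`, `n_gm`, `n_wm`, `n_total`, `metric`.
#' @export
sample_composition <- function(grid, gm_labels, wm_labels = "WM") {
  n <- nrow(grid)
  assert_that(n > 0, "grid has zero spots")
  n_gm <- sum(grid$region %in% gm_labels)
  n_wm <- sum(grid$region %in% wm_labels)
  list(sample_id = grid$sample_id[1L], n_gm = n_gm, n_wm = n_wm,
       n_total = n, metric = (n_gm - n_wm) / n)
}

#' Filter mapping samples by tissue composition
#'
#' Samples with metric strictly greater than `upper` (almost no white
#' matter) or strictly less than `lower` (white-matter-dominated) are
#' excluded; the boundaries themselves are retained.
#'
#' @param compositions List of [sample_composition()] results, or a data
#'   frame with `sample_id` and `metric`.
#' @param upper,lower Retention bounds.
#' @return Character vector of retained sample ids.
#' @export
filter_samples <- function(compositions, upper = 0.9, lower = -0.3) {
  if (is.data.frame(compositions)) {
    ids <- compositions$sample_id
    metric <- compositions$metric
  } else {
    ids <- vapply(compositions, `[[`, character(1), "sample_id")
    metric <- vapply(compositions, `[[`, numeric(1), "metric")
  }
  ids[metric >= lower & metric <= upper]
}

.default_simplify_map <- c(
  "L1" = "upper cortical", "L2/3" = "upper cortical", "L3/4" = "upper cortical",
  "L3-L5" = "lower cortical", "L5/6" = "lower cortical", "L6b" = "lower cortical",
  "WM" = "WM")

#' Consensus regional annotation across mapping samples
#'
#' Votes are counted over the retained samples only; each cell gets the most
#' frequently mapped region (ties to the lexicographically smallest label)
#' and a simplified label via `simplify_map`. Cells with zero retained
#' mappings are returned unannotated with `consensus_region = NA`.
#'
#' @param mappings A `cell_mappings` data frame (`cell_id`, `st_sample_id`,
#'   `region_label`).
#' @param retained Character vector of retained sample ids.
#' @param simplify_map Named region -> simplified-label map; regions absent
#'   from the map keep their own label.
#' @return Data frame: `cell_id`, `consensus_region`, `simplified`,
#'   `n_votes` (votes for the winner), `n_mapped` (retained mappings).
#' @export
consensus_region <- function(mappings, retained,
                             simplify_map = .default_simplify_map) {
  kept <- mappings[mappings$st_sample_id %in% retained, , drop = FALSE]
  cells <- unique(mappings$cell_id)
  rows <- lapply(cells, function(cid) {
    labs <- kept$region_label[kept$cell_id == cid]
    if (length(labs) == 0) {
      return(data.frame(cell_id = cid, consensus_region = NA_character_,
                        simplified = NA_character_, n_votes = 0L,
                        n_mapped = 0L, stringsAsFactors = FALSE))
    }
    win <- lex_mode(labs)
    simp <- if (win %in% names(simplify_map)) simplify_map[[win]] else win
    data.frame(cell_id = cid, consensus_region = win, simplified = simp,
               n_votes = sum(labs == win), n_mapped = length(labs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$n_mapped == 0)) {
    warnf("%d cell(s) had no retained mapping and are unannotated",
          sum(out$n_mapped == 0))
  }
  out
}
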