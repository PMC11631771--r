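#' Attribute spatial DEGs to cell populations via marker tables
#'
#' Each differentially expressed gene is assigned to the cell population with
#' the maximal marker effect size among the populations where it is a
#' marker; a DEG that is a marker nowhere is `"none"`. Exact effect-size
#' ties break to the lexicographically smallest population. Per (unit,
#' direction), the proportion of DEGs attributed to each population
#' (including `"none"`) is reported.
#'
#' @param degs Data frame with `gene`, `unit` (spatial region), `avg_log2FC`
#'   (direction = its sign); extra columns are carried through.
#' @param markers Data frame with `gene`, `population`, and the effect-size
#'   column; `(gene, population)` must be unique.
#' @param effect_col Name of the marker effect-size column.
#' @param marker_fdr Optional FDR cutoff applied to a `fdr` column of
#'   `markers` before matching.
#' @return List with `assignments` (degs plus `population`) and
#'   `proportions` (`unit`, `direction`, `population`, `n`, `proportion`;
#'   proportions sum to 1 within each (unit, direction)).
#' @export
deconvolve_degs <- function(degs, markers, effect_col = "avg_log2FC",
                            marker_fdr = NULL) {
  assert_that(nrow(degs) > 0 && nrow(markers) > 0,
              "degs and markers must be non-empty")
  assert_that(effect_col %in% names(markers),
              "markers lack effect column '%s'", effect_col)
  assert_that(!anyDuplicated(markers[, c("gene", "population")]),
              "duplicate (gene, population) marker rows",
              class = "spotnet_validation_error")
  if (!is.null(marker_fdr)) {
    assert_that("fdr" %in% names(markers), "marker_fdr needs an fdr column")
    markers <- markers[markers$fdr < marker_fdr, , drop = FALSE]
  }
  assign_one <- function(g) {
    hits <- markers[markers$gene == g, , drop = FALSE]
    if (nrow(hits) == 0) return("none")
    hits <- hits[order(-hits[[effect_col]], hits$population), , drop = FALSE]
    hits$population[1L]
  }
  degs$population <- vapply(degs$gene, assign_one, character(1))
  degs$direction <- ifelse(degs$avg_log2FC >= 0, "up", "down")

  props <- list()
  for (u in unique(degs$unit)) {
    for (dir in unique(degs$direction[degs$unit == u])) {
      sub <- degs[degs$unit == u & degs$direction == dir, ]
      tab <- table(sub$population)
      props[[length(props) + 1L]] <- data.frame(
        unit = u, direction = dir, population = names(tab),
        n = as.integer(tab), proportion = as.numeric(tab) / nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  list(assignments = degs, proportions = do.call(rbind, props))
}
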