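#' Read a tissue-positions CSV into a spot grid
#'
#' Accepts two dialects. The internal dialect has a header with columns
#' `barcode, in_tissue, array_row, array_col, x_um, y_um` (plus optional
#' `region`, `sample_id`). A 10x `tissue_positions_list.csv` without header
#' (barcode, in_tissue, array_row, array_col, pixel row, pixel col) is
#' auto-detected; reading it requires `pixels_per_um` so coordinates can be
#' converted to micrometers at ingest — all downstream computation is in
#' micrometers.
#'
#' Only `in_tissue == 1` rows are retained. Malformed input is rejected, not
#' repaired: missing columns and duplicated barcodes are errors.
#'
#' @param path CSV path.
#' @param spacing_um,diameter_um Lattice geometry recorded on the grid.
#' @param pixels_per_um Scale for the headerless 10x dialect; ignored for the
#'   internal dialect.
#' @param sample_id Sample id used if the file has no `sample_id` column.
#' @return A `spot_grid` data frame (see [make_hex_grid()]).
#' @export
read_tissue_positions <- function(path, spacing_um = 100, diameter_um = 55,
                                  pixels_per_um = NULL, sample_id = "S1") {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, fixed = TRUE)
  if (has_header) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("barcode", "in_tissue", "array_row", "array_col", "x_um", "y_um")
    miss <- setdiff(need, names(df))
    assert_that(length(miss) == 0, "positions file missing column(s): %s",
                paste(miss, collapse = ", "), class = "spotnet_format_error")
  } else {
    assert_that(!is.null(pixels_per_um),
                "headerless 10x positions need pixels_per_um",
                class = "spotnet_format_error")
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
    assert_that(ncol(df) >= 6, "10x positions need 6 columns",
                class = "spotnet_format_error")
    names(df)[1:6] <- c("barcode", "in_tissue", "array_row", "array_col",
                        "pxl_row", "pxl_col")
    df$x_um <- df$pxl_col / pixels_per_um
    df$y_um <- df$pxl_row / pixels_per_um
  }
  df <- df[df$in_tissue == 1, , drop = FALSE]
  assert_that(!anyDuplicated(df$barcode),
              "duplicated barcode(s): %s",
              paste(unique(df$barcode[duplicated(df$barcode)]), collapse = ", "),
              class = "spotnet_validation_error")
  assert_that(all(is.finite(df$x_um)) && all(is.finite(df$y_um)),
              "non-finite coordinates", class = "spotnet_validation_error")
  assert_that(diameter_um < spacing_um, "need diameter_um < spacing_um")
  if (is.null(df$region)) df$region <- "unknown"
  if (is.null(df$sample_id)) df$sample_id <- sample_id
  grid <- df[, c("barcode", "array_row", "array_col", "x_um", "y_um",
                 "region", "sample_id")]
  rownames(grid) <- NULL
  attr(grid, "spacing_um") <- spacing_um
  attr(grid, "diameter_um") <- diameter_um
  class(grid) <- c("spot_grid", "data.frame")
  grid
}

#' Write a spot grid as an internal-dialect positions CSV
#'
#' @param grid A `spot_grid`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tissue_positions <- function(grid, path) {
  df <- as.data.frame(grid)
  df <- data.frame(barcode = df$barcode, in_tissue = 1L,
                   array_row = df$array_row, array_col = df$array_col,
                   x_um = df$x_um, y_um = df$y_um,
                   region = df$region, sample_id = df$sample_id)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a MatrixMarket counts matrix with gene/barcode sidecars
#'
#' Genes are rows, spots are columns; a transposed matrix is detected from
#' sidecar lengths and flipped. Values must be non-negative integers; zeros
#' are implicit.
#'
#' @param matrix_path `.mtx` coordinate file.
#' @param genes_path,barcodes_path One identifier per line (TSV; first
#'   column used).
#' @return A `counts_table` (list with a dense `counts` matrix and
#'   `spot_meta`); see [simulate_counts()].
#' @export
read_counts_mtx <- function(matrix_path, genes_path, barcodes_path) {
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stopf("invalid MatrixMarket file: %s",
                                          conditionMessage(e),
                                          class = "spotnet_format_error"))
  genes <- utils::read.table(genes_path, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.table(barcodes_path, sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    # genes x spots as stored
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
    m <- Matrix::t(m)
  } else {
    stopf("matrix is %d x %d but sidecars have %d genes and %d barcodes",
          nrow(m), ncol(m), length(genes), length(barcodes),
          class = "spotnet_format_error")
  }
  assert_that(min(m) >= 0, "negative count value",
              class = "spotnet_validation_error")
  counts <- as.matrix(m)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes, barcodes)
  structure(list(
    counts = counts,
    spot_meta = data.frame(barcode = barcodes, total_umi = colSums(counts),
                           stringsAsFactors = FALSE),
    sample_meta = NULL, truth = NULL
  ), class = "counts_table")
}

#' Write a counts table as MatrixMarket plus sidecar TSVs
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` into `dir`.
#'
#' @param counts A `counts_table`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(inherits(counts, "counts_table"))
  m <- Matrix::Matrix(counts$counts, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

.default_binary_columns <- c(stain = "stain", x_um = "x_um", y_um = "y_um",
                             area_um2 = "area_um2", diameter_um = "diameter_um",
                             sample_id = "sample_id")

#' Read an amyloid binaries CSV
#'
#' Column names of image-analysis exports differ between setups, so the
#' mapping from internal names to file headers is configurable via
#' `column_map` (e.g. `c(x_um = "Center X")`). Rows with non-positive area
#' are rejected with their row number.
#'
#' @param path CSV path.
#' @param column_map Named character vector overriding entries of the default
#'   mapping; names are internal fields, values are file headers.
#' @param sample_id Fallback sample id if the file has no sample column.
#' @return An `amyloid_binaries` data frame.
#' @export
read_binaries_csv <- function(path, column_map = NULL, sample_id = "S1") {
  cmap <- .default_binary_columns
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("stain", "x_um", "y_um", "area_um2", "diameter_um")
  miss <- need[!cmap[need] %in% names(df)]
  assert_that(length(miss) == 0, "binaries file missing column(s): %s",
              paste(cmap[miss], collapse = ", "),
              class = "spotnet_format_error")
  out <- data.frame(stain = df[[cmap["stain"]]],
                    x_um = df[[cmap["x_um"]]], y_um = df[[cmap["y_um"]]],
                    area_um2 = df[[cmap["area_um2"]]],
                    diameter_um = df[[cmap["diameter_um"]]],
                    stringsAsFactors = FALSE)
  out$sample_id <- if (cmap["sample_id"] %in% names(df)) {
    df[[cmap["sample_id"]]]
  } else sample_id
  bad <- which(!(out$area_um2 > 0))
  assert_that(length(bad) == 0, "non-positive area at row %d", bad[1],
              class = "spotnet_validation_error")
  bad <- which(!(out$diameter_um > 0))
  assert_that(length(bad) == 0, "non-positive diameter at row %d", bad[1],
              class = "spotnet_validation_error")
  assert_that(all(out$stain %in% c("AmyloGlo", "OC")),
              "stain must be 'AmyloGlo' or 'OC'",
              class = "spotnet_validation_error")
  class(out) <- c("amyloid_binaries", "data.frame")
  out
}

#' Write an amyloid binaries table as CSV
#'
#' Fixed column order (`stain, x_um, y_um, area_um2, diameter_um,
#' sample_id`), so [read_binaries_csv()] round-trips it.
#'
#' @param binaries An `amyloid_binaries` data frame.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_binaries_csv <- function(binaries, path) {
  cols <- c("stain", "x_um", "y_um", "area_um2", "diameter_um", "sample_id")
  utils::write.csv(as.data.frame(binaries)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a result table as TSV with a header and fixed column order
#'
#' @param table A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
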