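#' Spot-by-gene count container for lattice spatial transcriptomics
#'
#' A `SpotMatrix` bundles a non-negative integer spot x gene count matrix with
#' spot barcodes, gene symbols and the tissue-positions table that places each
#' spot on the capture lattice. It is the substrate every pipeline stage
#' consumes.
#'
#' @param counts spots x genes matrix (dense or [Matrix::sparseMatrix()]),
#'   non-negative integers.
#' @param barcodes character vector of unique spot identifiers, one per row.
#' @param genes character vector of unique gene symbols, one per column.
#' @param positions a data frame with one row per spot: `barcode`,
#'   `in_tissue` (0/1), `array_row`, `array_col` (0-based lattice coordinates)
#'   and `pxl_row`, `pxl_col` pixel coordinates.
#'
#' @return An object of class `SpotMatrix`.
#' @examples
#' sm <- simulate_visium(sim_config(n_rows = 20, n_cols = 20, n_genes = 300,
#'                                  ring_width = 2, stroma_width = 1,
#'                                  seed = 1))$spots
#' sm
#' @export
spot_matrix <- function(counts, barcodes, genes, positions) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"),
    "generalMatrix"), "CsparseMatrix")
  positions <- tibble::as_tibble(positions)
  sm <- structure(
    list(counts = counts, barcodes = as.character(barcodes),
         genes = as.character(genes), positions = positions),
    class = "SpotMatrix"
  )
  validate_spot_matrix(sm)
}

validate_spot_matrix <- function(sm) {
  counts <- sm$counts
  assert_that(nrow(counts) == length(sm$barcodes),
              "count matrix row count does not match the number of barcodes")
  assert_that(ncol(counts) == length(sm$genes),
              "count matrix column count does not match the number of genes")
  assert_that(!anyDuplicated(sm$barcodes), "duplicate spot barcodes")
  assert_that(!anyDuplicated(sm$genes), "duplicate gene symbols")
  x <- counts@x
  assert_that(all(x >= 0), "counts must be non-negative")
  assert_that(all(x == round(x)), "counts must be integral")
  need <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row", "pxl_col")
  assert_that(all(need %in% names(sm$positions)),
              paste("positions table must contain columns:",
                    paste(need, collapse = ", ")))
  assert_that(setequal(sm$positions$barcode, sm$barcodes) &&
                nrow(sm$positions) == length(sm$barcodes),
              "positions table must have exactly one row per barcode")
  intis <- sm$positions[sm$positions$in_tissue == 1, ]
  assert_that(!anyDuplicated(intis[c("array_row", "array_col")]),
              "in-tissue spots must occupy unique lattice coordinates")
  rownames(sm$counts) <- sm$barcodes
  colnames(sm$counts) <- sm$genes
  # align positions to matrix row order
  sm$positions <- sm$positions[match(sm$barcodes, sm$positions$barcode), ]
  sm
}

#' @export
print.SpotMatrix <- function(x, ...) {
  cat("<SpotMatrix> ", nrow(x$counts), " spots x ", ncol(x$counts),
      " genes (", sum(x$positions$in_tissue == 1), " in tissue)\n", sep = "")
  invisible(x)
}

#' @export
dim.SpotMatrix <- function(x) dim(x$counts)

#' Restrict a SpotMatrix to a subset of spots
#'
#' @param sm a [spot_matrix()].
#' @param barcodes barcodes to keep (order preserved).
#' @return A `SpotMatrix` with only the requested spots.
#' @export
subset_spots <- function(sm, barcodes) {
  assert_that(all(barcodes %in% sm$barcodes), "unknown barcodes in subset")
  keep <- match(barcodes, sm$barcodes)
  spot_matrix(sm$counts[keep, , drop = FALSE], sm$barcodes[keep], sm$genes,
              sm$positions[match(barcodes, sm$positions$barcode), ])
}
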