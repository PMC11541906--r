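# Readers/writers for the on-disk formats the pipeline touches:
# MatrixMarket counts with features/barcodes sidecars, the 10x
# tissue-positions CSV dialect, gene-position tables, gene signatures and
# ligand-receptor pair tables.

#' Write a SpotMatrix to a 10x-style directory
#'
#' Writes `matrix.mtx` (genes x spots, MatrixMarket), `features.tsv`,
#' `barcodes.tsv` and `tissue_positions.csv` (columns barcode, in_tissue,
#' array_row, array_col, pxl_row, pxl_col).
#'
#' @param sm a [spot_matrix()].
#' @param out_dir directory to create/write into.
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_spot_matrix <- function(sm, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    assert_that(ok, paste("cannot create directory", out_dir))
  }
  paths <- c(
    matrix = file.path(out_dir, "matrix.mtx"),
    features = file.path(out_dir, "features.tsv"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    positions = file.path(out_dir, "tissue_positions.csv")
  )
  Matrix::writeMM(methods::as(Matrix::t(sm$counts), "CsparseMatrix"),
                  paths[["matrix"]])
  writeLines(sm$genes, paths[["features"]])
  writeLines(sm$barcodes, paths[["barcodes"]])
  readr::write_csv(sm$positions[, c("barcode", "in_tissue", "array_row",
                                    "array_col", "pxl_row", "pxl_col")],
                   paths[["positions"]])
  invisible(paths)
}

#' Read a SpotMatrix from MatrixMarket + sidecar files
#'
#' @param matrix_path MatrixMarket file, genes x spots (10x convention).
#' @param features_path one gene symbol per line.
#' @param barcodes_path one barcode per line.
#' @param positions_path tissue-positions CSV (barcode, in_tissue, array_row,
#'   array_col, pxl_row, pxl_col).
#' @param in_tissue_only drop spots flagged `in_tissue == 0` (default TRUE).
#' @return A validated [spot_matrix()].
#' @export
read_spot_matrix <- function(matrix_path, features_path, barcodes_path,
                             positions_path, in_tissue_only = TRUE) {
  for (p in c(matrix_path, features_path, barcodes_path, positions_path)) {
    assert_that(file.exists(p), paste("file not found:", p))
  }
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(features_path)
  barcodes <- readLines(barcodes_path)
  assert_that(nrow(m) == length(genes),
              "matrix row count does not match features file")
  assert_that(ncol(m) == length(barcodes),
              "matrix column count does not match barcodes file")
  pos <- readr::read_csv(positions_path, show_col_types = FALSE)
  sm <- spot_matrix(Matrix::t(m), barcodes, genes, pos)
  if (in_tissue_only && any(sm$positions$in_tissue == 0)) {
    sm <- subset_spots(sm, sm$positions$barcode[sm$positions$in_tissue == 1])
  }
  sm
}

# Natural chromosome ordering: chr1 < chr2 < ... < chr10 < chrX < chrY < chrM;
# labels outside that scheme keep file order.
chromosome_levels <- function(chroms) {
  u <- unique(chroms)
  core <- sub("^chr", "", u, ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(core))
  special <- match(toupper(core), c("X", "Y", "M", "MT"))
  if (all(!is.na(num) | !is.na(special))) {
    key <- ifelse(is.na(num), 1e6 + special, num)
    u[order(key)]
  } else {
    u
  }
}

#' Read a gene-position table
#'
#' Tab-delimited with columns `gene`, `chrom`, `start`, `end` (1-based,
#' inclusive). Rows are sorted by (chromosome order, start) and a
#' within-chromosome `rank` is assigned; this sorted order is the canonical
#' gene order used by chromosome-window smoothing.
#'
#' @param path TSV file path.
#' @return A tibble: gene, chrom, start, end, rank.
#' @export
read_gene_positions <- function(path) {
  gp <- readr::read_tsv(path, show_col_types = FALSE)
  gene_position_table(gp)
}

#' Validate and canonically sort a gene-position data frame
#'
#' @param gp data frame with columns gene, chrom, start, end.
#' @return A tibble sorted by (chromosome order, start) with per-chromosome
#'   `rank` starting at 1.
#' @export
gene_position_table <- function(gp) {
  need <- c("gene", "chrom", "start", "end")
  assert_that(all(need %in% names(gp)),
              "gene-position table needs columns gene, chrom, start, end")
  assert_that(!anyDuplicated(gp$gene), "duplicate gene in position table")
  assert_that(all(gp$start <= gp$end), "gene with start > end")
  gp <- tibble::as_tibble(gp)
  gp$chrom <- factor(gp$chrom, levels = chromosome_levels(gp$chrom))
  gp <- dplyr::arrange(gp, .data$chrom, .data$start, .data$gene)
  gp <- dplyr::mutate(dplyr::group_by(gp, .data$chrom),
                      rank = dplyr::row_number())
  gp <- dplyr::ungroup(gp)
  gp$chrom <- as.character(gp$chrom)
  gp
}

#' Construct a gene signature
#'
#' @param name signature name.
#' @param genes non-empty character vector of unique gene symbols.
#' @param classes optional per-gene class labels (e.g. "immunoglobulin").
#' @return An object of class `GeneSignature`: a list with `name`, `genes`
#'   and `classes`.
#' @export
gene_signature <- function(name, genes, classes = NULL) {
  assert_that(length(genes) >= 1, "signature gene list must be non-empty")
  assert_that(!anyDuplicated(genes),
              paste0("duplicate genes in signature '", name, "'"))
  if (!is.null(classes)) {
    assert_that(length(classes) == length(genes),
                "classes must align with genes")
  }
  structure(list(name = name, genes = as.character(genes), classes = classes),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat("<GeneSignature> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read a gene signature from TSV or JSON
#'
#' TSV: columns `gene` and optional `class`; the signature name is taken from
#' the file name. JSON: an object with `name`, `genes` and optional `classes`.
#'
#' @param path signature file.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(gene_signature(obj$name %||% basename(path), obj$genes,
                          obj$classes))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  assert_that("gene" %in% names(tab), "signature TSV needs a 'gene' column")
  gene_signature(sub("\\.[^.]*$", "", basename(path)), tab$gene,
                 if ("class" %in% names(tab)) tab$class else NULL)
}

#' Bundled gene signatures
#'
#' Ships the signatures the pipeline uses out of the box: `immune_panel`
#' (pan-immune, T, B and myeloid markers used for the spot immune score),
#' `tls_29gene` (a 29-gene tertiary-lymphoid-structure signature dominated by
#' immunoglobulin genes) and `activation_5gene` (a compact plasma-cell /
#' chemokine immune-activation signature).
#'
#' @param name one of `"immune_panel"`, `"tls_29gene"`, `"activation_5gene"`.
#' @return A [gene_signature()].
#' @export
bundled_signature <- function(name = c("immune_panel", "tls_29gene",
                                       "activation_5gene")) {
  name <- match.arg(name)
  read_signature(system.file("extdata", paste0(name, ".tsv"),
                             package = "spatialtme", mustWork = TRUE))
}

#' Read a ligand-receptor pair table
#'
#' Tab-delimited with columns `ligand`, `receptor_subunits` (semicolon-joined
#' for multi-subunit receptors) and `pathway`.
#'
#' @param path TSV file; default the bundled table covering the SPP1, MIF,
#'   CCL and CXCL pathways.
#' @return A tibble: ligand, receptor_subunits (list column), pathway.
#' @export
read_lr_pairs <- function(path = system.file("extdata", "lr_pairs.tsv",
                                             package = "spatialtme",
                                             mustWork = TRUE)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("ligand", "receptor_subunits", "pathway")
  assert_that(all(need %in% names(tab)),
              "ligand-receptor table needs ligand, receptor_subunits, pathway")
  assert_that(all(nzchar(tab$ligand)) && all(nzchar(tab$receptor_subunits)),
              "ligand and receptor sets must be non-empty")
  tab$receptor_subunits <- strsplit(tab$receptor_subunits, ";", fixed = TRUE)
  tibble::as_tibble(tab)
}
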