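# Depth normalization and highly-variable-gene selection.

#' Depth-normalize and log-transform counts
#'
#' Each spot's counts are scaled to a common total (`scale_target`, default
#' the median library size of non-empty spots) and log1p-transformed. Spots
#' with zero total counts are emitted as all-zero rows with a warning.
#'
#' @param sm a [spot_matrix()].
#' @param scale_target per-spot total after scaling; `NULL` uses the median
#'   library size.
#' @return A `NormalizedMatrix`: list with `values` (sparse spots x genes
#'   log-normalized matrix), `scale_target`, `lib_sizes`, `mean_counts`
#'   (per-gene raw mean, used by the CNV gene filter), `barcodes`, `genes`,
#'   `positions`.
#' @export
normalize_counts <- function(sm, scale_target = NULL) {
  assert_that(inherits(sm, "SpotMatrix"), "sm must be a SpotMatrix")
  lib <- Matrix::rowSums(sm$counts)
  if (any(lib == 0)) {
    warn(paste(sum(lib == 0), "spot(s) with zero total counts kept as",
               "all-zero rows"))
  }
  if (is.null(scale_target)) scale_target <- median(lib[lib > 0])
  assert_that(is.numeric(scale_target) && scale_target > 0,
              "scale_target must be positive")
  sf <- ifelse(lib > 0, scale_target / lib, 0)
  values <- Matrix::Diagonal(x = sf) %*% sm$counts
  values@x <- log1p(values@x)
  dimnames(values) <- list(sm$barcodes, sm$genes)
  structure(list(
    values = methods::as(values, "CsparseMatrix"),
    scale_target = scale_target,
    lib_sizes = lib,
    mean_counts = Matrix::colMeans(sm$counts),
    barcodes = sm$barcodes, genes = sm$genes,
    positions = sm$positions
  ), class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("<NormalizedMatrix> ", length(x$barcodes), " spots x ",
      length(x$genes), " genes (scale target ",
      format(x$scale_target), ")\n", sep = "")
  invisible(x)
}

#' Select highly variable genes
#'
#' Genes are ranked by a binned dispersion statistic: dispersion
#' (variance / mean of the log-normalized values) is z-standardized within
#' 20 gene-mean bins so that selection is not driven by expression level.
#'
#' @param nm a [normalize_counts()] result.
#' @param n_top number of genes to return (clipped to the gene count).
#' @param n_bins number of mean bins for dispersion standardization.
#' @return Character vector of gene names, most variable first.
#' @export
select_hvg <- function(nm, n_top = 2000, n_bins = 20) {
  assert_that(is_count(n_top) && n_top >= 1, "n_top must be >= 1")
  v <- nm$values
  mu <- Matrix::colMeans(v)
  ex2 <- Matrix::colMeans(v^2)
  n <- nrow(v)
  sigma2 <- (ex2 - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0, sigma2 / mu, 0)
  bin <- cut(mu, breaks = unique(quantile(mu, probs = seq(0, 1,
                                                          length.out = n_bins + 1))),
             include.lowest = TRUE)
  z <- numeric(length(disp))
  for (ii in split(seq_along(disp), bin)) {
    d <- disp[ii]
    s <- sd(d)
    z[ii] <- if (is.na(s) || s == 0) 0 else (d - mean(d)) / s
  }
  # constant genes can never outrank a variable gene
  ord <- order(sigma2 == 0, -z, -disp, nm$genes)
  nm$genes[ord][seq_len(min(n_top, length(ord)))]
}
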