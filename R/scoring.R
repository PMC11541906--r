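# Signature scoring (immune score, TLS score, activation signatures) and
# immune-score-driven reference-cluster selection.

#' Score spots against a gene signature
#'
#' The score is the unweighted mean of log-normalized expression over the
#' signature genes present in the matrix; missing genes are dropped (never
#' zero-filled), so adding a gene absent from the matrix cannot change the
#' scores.
#'
#' @param nm a [normalize_counts()] result.
#' @param sig a [gene_signature()] (or character vector of genes).
#' @return tibble (barcode, score) with attributes `signature` (name) and
#'   `genes_used`.
#' @export
score_signature <- function(nm, sig) {
  if (is.character(sig)) sig <- gene_signature("signature", sig)
  present <- intersect(sig$genes, nm$genes)
  if (length(present) == 0) {
    abort(paste0("signature '", sig$name,
                 "' has no genes present in the matrix"))
  }
  score <- Matrix::rowMeans(nm$values[, present, drop = FALSE])
  structure(
    tibble::tibble(barcode = nm$barcodes, score = as.numeric(score)),
    signature = sig$name, genes_used = present
  )
}

#' Select the reference cluster by median immune score
#'
#' Returns the cluster whose within-cluster median score is maximal; exact
#' ties are broken toward the smaller cluster label. The selected cluster is
#' assumed copy-number neutral and anchors CNV inference.
#'
#' @param scores tibble (barcode, score) from [score_signature()].
#' @param labels tibble (barcode, cluster) from [cluster_spots()].
#' @return The selected cluster id (same type as `labels$cluster`).
#' @export
select_reference_cluster <- function(scores, labels) {
  joined <- dplyr::inner_join(scores, labels, by = "barcode")
  assert_that(nrow(joined) > 0, "scores and labels share no barcodes")
  med <- dplyr::summarise(dplyr::group_by(joined, .data$cluster),
                          median_score = median(.data$score),
                          .groups = "drop")
  med <- dplyr::arrange(med, dplyr::desc(.data$median_score), .data$cluster)
  med$cluster[1]
}
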