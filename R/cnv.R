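# Copy-number inference from expression, relative to an immune reference:
# reference-centered relative expression -> chromosome-window smoothing ->
# six-state discretization -> |state - 3| CNV scoring -> Ward subclustering
# -> malignant-cluster calling.

#' Reference-centered relative expression
#'
#' Genes with mean raw count below `cutoff` are removed, each remaining
#' gene's log-normalized values are centered on the reference-spot mean, and
#' the result is clipped to `[-clip, clip]` (the clipping plays the
#' denoising role: single-gene outliers cannot dominate a window).
#'
#' @param nm a [normalize_counts()] result.
#' @param reference_barcodes barcodes of the reference (copy-number-neutral)
#'   spots.
#' @param clip symmetric clipping bound (default 0.3).
#' @param cutoff minimum per-gene mean raw count (default 0.1).
#' @return Dense spots x genes matrix with dimnames.
#' @export
compute_relative_expression <- function(nm, reference_barcodes, clip = 0.3,
                                        cutoff = 0.1) {
  assert_that(length(reference_barcodes) > 0,
              "reference spot set must be non-empty")
  assert_that(all(reference_barcodes %in% nm$barcodes),
              "reference barcodes missing from the matrix")
  keep <- nm$mean_counts >= cutoff
  if (!any(keep)) abort("no genes pass the mean-count cutoff")
  v <- as.matrix(nm$values[, keep, drop = FALSE])
  ref_mean <- colMeans(v[nm$barcodes %in% reference_barcodes, , drop = FALSE])
  rel <- sweep(v, 2, ref_mean)
  rel[rel > clip] <- clip
  rel[rel < -clip] <- -clip
  rel
}

#' Moving-average smoothing along each chromosome
#'
#' A centered moving average over the canonical within-chromosome gene order
#' (window shrinks symmetrically at chromosome edges); windows never span
#' chromosomes. Genes absent from the position table are dropped with a
#' message.
#'
#' @param rel spots x genes matrix (e.g. [compute_relative_expression()]).
#' @param gene_positions tibble from [gene_position_table()].
#' @param window odd window width in genes (default 101).
#' @return spots x genes matrix in canonical chromosome order.
#' @export
smooth_along_chromosome <- function(rel, gene_positions, window = 101) {
  assert_that(window >= 1 && window %% 2 == 1, "window must be odd and >= 1")
  gp <- gene_positions[gene_positions$gene %in% colnames(rel), ]
  dropped <- ncol(rel) - nrow(gp)
  if (dropped > 0) {
    inform(paste(dropped, "gene(s) absent from the position table excluded",
                 "from CNV smoothing"))
  }
  assert_that(nrow(gp) > 0, "no genes shared with the position table")
  out <- matrix(0, nrow(rel), nrow(gp),
                dimnames = list(rownames(rel), gp$gene))
  for (ch in unique(gp$chrom)) {
    genes <- gp$gene[gp$chrom == ch]
    block <- rel[, genes, drop = FALSE]
    out[, genes] <- as.matrix(block %*% ma_operator(length(genes), window))
  }
  out
}

#' Discretize smoothed ratios into six copy-number states
#'
#' Deterministic symmetric thresholding standing in for a six-state HMM:
#' state 3 is copy-neutral (values in the open interval `(-t1, t1)`), states
#' 2/1 are moderate/strong loss, states 4/5/6 increasing gain. Default
#' thresholds are `clip * c(-2/3, -1/3, 1/3, 2/3, 1)`, i.e.
#' `(-0.2, -0.1, 0.1, 0.2, 0.3)` at the default clip of 0.3.
#'
#' @param smoothed matrix from [smooth_along_chromosome()].
#' @param thresholds strictly increasing numeric vector of length 5.
#' @param clip clip bound used to derive default thresholds.
#' @return Integer matrix of states in `{1..6}` with the input's dimnames.
#' @export
discretize_states <- function(smoothed, thresholds = NULL, clip = 0.3) {
  if (is.null(thresholds)) thresholds <- clip * c(-2, -1, 1, 2, 3) / 3
  assert_that(length(thresholds) == 5 && all(diff(thresholds) > 0),
              "thresholds must be 5 strictly increasing values")
  x <- smoothed
  s <- matrix(3L, nrow(x), ncol(x), dimnames = dimnames(x))
  s[x <= thresholds[1]] <- 1L
  s[x > thresholds[1] & x <= thresholds[2]] <- 2L
  s[x >= thresholds[3] & x < thresholds[4]] <- 4L
  s[x >= thresholds[4] & x < thresholds[5]] <- 5L
  s[x >= thresholds[5]] <- 6L
  s
}

#' Ward subclustering of smoothed CNV profiles
#'
#' Hierarchical clustering (Ward linkage on Euclidean distances) of the
#' non-reference ("observation") spots, cut into `k` clusters; reference
#' spots are labeled `"reference"`.
#'
#' @param smoothed matrix from [smooth_along_chromosome()].
#' @param k number of observation clusters (default 8).
#' @param reference_barcodes spots excluded from clustering.
#' @return tibble (barcode, cnv_cluster) with character labels `"1"..k` and
#'   `"reference"`.
#' @export
subcluster_spots <- function(smoothed, k = 8, reference_barcodes = character()) {
  assert_that(is_count(k) && k >= 1, "k must be a positive integer")
  obs <- setdiff(rownames(smoothed), reference_barcodes)
  assert_that(k <= length(obs),
              "k exceeds the number of non-reference spots")
  hc <- hclust(dist(smoothed[obs, , drop = FALSE]), method = "ward.D2")
  cl <- cutree(hc, k = k)
  tibble::tibble(
    barcode = rownames(smoothed),
    cnv_cluster = ifelse(rownames(smoothed) %in% obs,
                         as.character(cl[match(rownames(smoothed), obs)]),
                         "reference")
  )
}

#' CNV scores from discretized states
#'
#' Per (gene, spot) the CNV score is `|state - 3|`; the per-spot score sums
#' it over genes; the per-cluster score sums, over genes, the within-cluster
#' mean of `|state - 3|` (so duplicating spots leaves it unchanged).
#'
#' @param states integer matrix from [discretize_states()].
#' @param labels tibble (barcode, cnv_cluster) from [subcluster_spots()].
#' @return list of tibbles: `spot` (barcode, cnv_cluster, cnv_score),
#'   `cluster` (cnv_cluster, cnv_score, n_spots), `gene` (gene, mean_score).
#' @export
cnv_scores <- function(states, labels) {
  labels <- labels[match(rownames(states), labels$barcode), ]
  dev <- abs(states - 3)
  spot <- tibble::tibble(
    barcode = rownames(states),
    cnv_cluster = labels$cnv_cluster,
    cnv_score = unname(rowSums(dev))
  )
  cluster <- dplyr::group_by(spot, .data$cnv_cluster)
  # sum over genes of the within-cluster mean |state - 3| equals the
  # within-cluster mean of per-spot sums
  cluster <- dplyr::summarise(cluster, cnv_score = mean(.data$cnv_score),
                              n_spots = dplyr::n(), .groups = "drop")
  gene <- tibble::tibble(gene = colnames(states),
                         mean_score = unname(colMeans(dev)))
  list(spot = spot, cluster = cluster, gene = gene)
}

#' Call malignant clusters from CNV scores
#'
#' A cluster is flagged malignant when its CNV score exceeds `theta` times
#' the median cluster score. If no cluster passes but a unique top-scoring
#' cluster with positive score exists, that cluster is flagged (the
#' fallback is disabled by ties). The `"reference"` cluster is never
#' malignant. All-zero scores yield no malignant clusters with a warning.
#'
#' @param cluster_scores tibble (cnv_cluster, cnv_score) from
#'   [cnv_scores()]`$cluster`.
#' @param theta multiple of the median cluster score (default 2).
#' @return The input tibble with a logical `malignant` column.
#' @export
call_tumor_clusters <- function(cluster_scores, theta = 2) {
  obs <- cluster_scores[cluster_scores$cnv_cluster != "reference", ]
  assert_that(nrow(obs) >= 2, "need at least 2 observation clusters")
  d <- obs$cnv_score
  if (all(d == 0)) {
    warn("all cluster CNV scores are zero; no malignant clusters")
    flag <- rep(FALSE, nrow(obs))
  } else {
    flag <- d > theta * median(d)
    if (!any(flag) && sum(d == max(d)) == 1) {
      flag[which.max(d)] <- TRUE
    }
    if (!any(flag)) {
      warn("no cluster exceeds the malignancy threshold (tied top scores)")
    }
  }
  out <- cluster_scores
  out$malignant <- FALSE
  out$malignant[match(obs$cnv_cluster, out$cnv_cluster)] <- flag
  out
}

#' End-to-end CNV inference and malignant-spot calling
#'
#' Composes [compute_relative_expression()], [smooth_along_chromosome()],
#' [discretize_states()], [subcluster_spots()], [cnv_scores()] and
#' [call_tumor_clusters()].
#'
#' @param nm a [normalize_counts()] result.
#' @param reference_barcodes reference (copy-number-neutral) spot barcodes.
#' @param gene_positions tibble from [gene_position_table()].
#' @param window,clip,cutoff,k,theta stage parameters (see the stage
#'   functions).
#' @return list of class `cnv_result`: `smoothed`, `states`, `scores`
#'   (from [cnv_scores()]), `clusters` (cluster calls with `malignant`),
#'   `spot_calls` (tibble barcode, cnv_cluster, cnv_score, malignant).
#' @export
infer_cnv <- function(nm, reference_barcodes, gene_positions, window = 101,
                      clip = 0.3, cutoff = 0.1, k = 8, theta = 2) {
  rel <- compute_relative_expression(nm, reference_barcodes, clip = clip,
                                     cutoff = cutoff)
  smoothed <- smooth_along_chromosome(rel, gene_positions, window = window)
  states <- discretize_states(smoothed, clip = clip)
  labels <- subcluster_spots(smoothed, k = k,
                             reference_barcodes = reference_barcodes)
  scores <- cnv_scores(states, labels)
  calls <- call_tumor_clusters(scores$cluster, theta = theta)
  spot_calls <- dplyr::left_join(
    scores$spot,
    calls[, c("cnv_cluster", "malignant")],
    by = "cnv_cluster"
  )
  structure(list(smoothed = smoothed, states = states, scores = scores,
                 clusters = calls, spot_calls = spot_calls),
            class = "cnv_result")
}

#' @export
print.cnv_result <- function(x, ...) {
  n_mal <- sum(x$spot_calls$malignant)
  cat("<cnv_result> ", nrow(x$spot_calls), " spots, ",
      nrow(x$clusters), " clusters, ", n_mal, " malignant spots\n", sep = "")
  invisible(x)
}
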