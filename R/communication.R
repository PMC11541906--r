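# Ligand-receptor communication between spot clusters: mass-action product
# scores with a cluster-label permutation null, and outgoing/incoming
# signaling-role summaries.

# cluster-wise mean expression and detection fraction for the genes a pair
# table needs; `order` fixes the cluster order across permutations
cluster_gene_stats <- function(v, cluster, clusters) {
  ind <- Matrix::sparseMatrix(
    i = seq_along(cluster), j = match(cluster, clusters), x = 1,
    dims = c(length(cluster), length(clusters))
  )
  n_k <- Matrix::colSums(ind)
  means <- as.matrix(Matrix::crossprod(v, ind)) /
    rep(n_k, each = ncol(v))
  pct <- as.matrix(Matrix::crossprod(v > 0, ind)) /
    rep(n_k, each = ncol(v))
  dimnames(means) <- dimnames(pct) <- list(colnames(v), clusters)
  list(means = means, pct = pct)
}

# score all (sender, receiver, pair) combinations from cluster stats
pair_scores <- function(stats, pairs, min_pct) {
  k <- colnames(stats$means)
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    lig <- pairs$ligand[i]
    rec <- pairs$receptor_subunits[[i]]
    mean_l <- stats$means[lig, ]
    mean_l[stats$pct[lig, ] < min_pct] <- 0
    rec_mat <- stats$means[rec, , drop = FALSE]
    # geometric mean across subunits; any zero subunit zeroes the receiver
    mean_r <- exp(colMeans(log(pmax(rec_mat, 0)))) *
      as.numeric(apply(rec_mat > 0, 2, all))
    grid <- expand.grid(sender = k, receiver = k, stringsAsFactors = FALSE)
    tibble::tibble(
      sender = grid$sender, receiver = grid$receiver,
      ligand = lig, receptor = paste(rec, collapse = ";"),
      pathway = pairs$pathway[i],
      score = unname(mean_l[grid$sender] * mean_r[grid$receiver])
    )
  })
}

prepare_lr_inputs <- function(nm, labels, pairs) {
  labels <- labels[match(nm$barcodes, labels$barcode), ]
  cluster <- as.character(labels$cluster)
  clusters <- sort(unique(cluster))
  assert_that(length(clusters) >= 2, "need at least 2 clusters")
  ok <- vapply(seq_len(nrow(pairs)), function(i) {
    all(c(pairs$ligand[i], pairs$receptor_subunits[[i]]) %in% nm$genes)
  }, logical(1))
  if (any(!ok)) {
    inform(paste(sum(!ok), "ligand-receptor pair(s) skipped: genes absent",
                 "from the matrix"))
  }
  pairs <- pairs[ok, ]
  assert_that(nrow(pairs) > 0, "no ligand-receptor pair has all genes present")
  genes <- unique(c(pairs$ligand, unlist(pairs$receptor_subunits)))
  list(v = nm$values[, genes, drop = FALSE], cluster = cluster,
       clusters = clusters, pairs = pairs)
}

#' Ligand-receptor communication scores between clusters
#'
#' The communication score for (sender A, receiver B, pair) is the product
#' of the mean normalized ligand expression in A and the geometric mean,
#' across receptor subunits, of mean normalized expression in B. Pairs whose
#' ligand is detected in fewer than `min_pct` of sender spots score 0.
#'
#' @param nm a [normalize_counts()] result.
#' @param labels tibble (barcode, cluster).
#' @param pairs a [read_lr_pairs()] tibble; pairs with genes absent from the
#'   matrix are skipped with a message.
#' @param min_pct minimum ligand detection fraction in the sender.
#' @return tibble: sender, receiver, ligand, receptor, pathway, score.
#' @export
lr_scores <- function(nm, labels, pairs = read_lr_pairs(), min_pct = 0.1) {
  inp <- prepare_lr_inputs(nm, labels, pairs)
  stats <- cluster_gene_stats(inp$v, inp$cluster, inp$clusters)
  pair_scores(stats, inp$pairs, min_pct)
}

#' Permutation test for ligand-receptor scores
#'
#' Cluster labels are permuted across spots `n_permutations` times and each
#' interaction's p-value is the add-one estimator
#' `(1 + #\{permuted score >= observed\}) / (n_permutations + 1)`.
#'
#' @inheritParams lr_scores
#' @param n_permutations number of label permutations (>= 19).
#' @param seed RNG seed for the permutations.
#' @return The [lr_scores()] tibble with `p_value` and `n_permutations`.
#' @export
lr_permutation_test <- function(nm, labels, pairs = read_lr_pairs(),
                                n_permutations = 100, seed = 0,
                                min_pct = 0.1) {
  assert_that(is_count(n_permutations) && n_permutations >= 19,
              "need at least 19 permutations")
  inp <- prepare_lr_inputs(nm, labels, pairs)
  obs <- pair_scores(cluster_gene_stats(inp$v, inp$cluster, inp$clusters),
                     inp$pairs, min_pct)
  exceed <- rep(0L, nrow(obs))
  with_seed(stream_seed(seed, "perm"), {
    for (b in seq_len(n_permutations)) {
      perm <- sample(inp$cluster)
      ps <- pair_scores(cluster_gene_stats(inp$v, perm, inp$clusters),
                        inp$pairs, min_pct)
      exceed <- exceed + as.integer(ps$score >= obs$score)
    }
  })
  obs$p_value <- (1 + exceed) / (n_permutations + 1)
  obs$n_permutations <- n_permutations
  obs
}

#' Outgoing and incoming signaling roles per cluster
#'
#' Sums interaction scores by sender (outgoing) and receiver (incoming);
#' total outgoing mass equals total incoming mass exactly. Optionally keeps
#' only interactions with `p_value <= alpha`.
#'
#' @param interactions an [lr_scores()] or [lr_permutation_test()] tibble.
#' @param alpha optional significance filter (requires a `p_value` column).
#' @return tibble: cluster, outgoing, incoming.
#' @export
signaling_roles <- function(interactions, alpha = NULL) {
  assert_that(nrow(interactions) > 0, "empty interaction table")
  if (!is.null(alpha)) {
    assert_that("p_value" %in% names(interactions),
                "alpha filtering needs a p_value column")
    interactions <- interactions[interactions$p_value <= alpha, ]
  }
  clusters <- sort(unique(c(interactions$sender, interactions$receiver)))
  out <- dplyr::summarise(dplyr::group_by(interactions, .data$sender),
                          outgoing = sum(.data$score), .groups = "drop")
  inc <- dplyr::summarise(dplyr::group_by(interactions, .data$receiver),
                          incoming = sum(.data$score), .groups = "drop")
  res <- tibble::tibble(cluster = clusters)
  res$outgoing <- out$outgoing[match(clusters, out$sender)]
  res$incoming <- inc$incoming[match(clusters, inc$receiver)]
  res$outgoing[is.na(res$outgoing)] <- 0
  res$incoming[is.na(res$incoming)] <- 0
  res
}
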