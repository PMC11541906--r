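# Spot clustering (PCA -> SNN graph -> modularity communities) and
# one-vs-rest marker detection with the standard min.pct / log-fold-change
# emission filters.

#' Cluster spots on an SNN graph
#'
#' PCA on the (scaled) highly-variable-gene submatrix, a shared-nearest-
#' neighbor graph with Jaccard edge weights, then Louvain modularity
#' community detection at the given resolution. Deterministic for a fixed
#' `seed`.
#'
#' @param nm a [normalize_counts()] result.
#' @param resolution community-detection resolution (default 0.8).
#' @param n_pcs number of principal components (default 30; clipped with a
#'   warning when the matrix is smaller).
#' @param k_neighbors neighbors per spot for the SNN graph.
#' @param hvg character vector of genes to embed; `NULL` selects the top
#'   2000 by [select_hvg()].
#' @param seed RNG seed for the community detection.
#' @return A tibble (barcode, cluster) with 0-based integer cluster labels
#'   ordered by decreasing cluster size; attributes `resolution`, `n_pcs`,
#'   `k_neighbors`.
#' @export
cluster_spots <- function(nm, resolution = 0.8, n_pcs = 30, k_neighbors = 15,
                          hvg = NULL, seed = 0) {
  assert_that(length(nm$barcodes) >= 2, "need at least 2 spots")
  assert_that(resolution > 0, "resolution must be > 0")
  if (is.null(hvg)) hvg <- select_hvg(nm, 2000)
  x <- as.matrix(nm$values[, hvg, drop = FALSE])
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0 | is.nan(colSums(x))] <- 0
  max_pcs <- min(dim(x)) - 1L
  if (n_pcs > max_pcs) {
    warn(paste("n_pcs clipped to", max_pcs))
    n_pcs <- max_pcs
  }
  if (n_pcs < 1 || sum(x != 0) == 0) {
    # degenerate input (e.g. all spots identical): one cluster
    out <- tibble::tibble(barcode = nm$barcodes, cluster = 0L)
    return(structure(out, resolution = resolution, n_pcs = n_pcs,
                     k_neighbors = k_neighbors))
  }
  pcs <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)$x
  g <- snn_graph(pcs, k_neighbors)
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  # relabel 0-based by decreasing size (ties: first-seen order)
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- tibble::tibble(barcode = nm$barcodes,
                        cluster = unname(relab[as.character(memb)]))
  structure(out, resolution = resolution, n_pcs = n_pcs,
            k_neighbors = k_neighbors)
}

# Shared-nearest-neighbor graph with Jaccard weights, pruning edges with
# Jaccard <= 1/k (the conventional cutoff).
snn_graph <- function(pcs, k) {
  n <- nrow(pcs)
  k <- min(k, n - 1L)
  d <- as.matrix(dist(pcs))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k + 1L)]))
  a <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1L), j = as.vector(t(nn)), x = 1,
    dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(a)
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1L) - jac@x)
  jac <- jac * (jac > 1 / k)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
}

#' One-vs-rest differential expression per cluster
#'
#' For each cluster, genes passing the detection and fold-change filters
#' (`max(pct_in, pct_out) >= min_pct` and `|avg_log2FC| >= logfc_threshold`)
#' are tested with the Wilcoxon rank-sum test; p-values are BH-adjusted
#' within cluster. `avg_log2FC = log2((mean(expm1 in) + 1) /
#' (mean(expm1 out) + 1))`.
#'
#' @param nm a [normalize_counts()] result.
#' @param labels tibble (barcode, cluster) from [cluster_spots()].
#' @param min_pct minimum detection fraction in either group (default 0.1).
#' @param logfc_threshold minimum |avg_log2FC| (default 0.25).
#' @return tibble: cluster, gene, avg_log2FC, pct_in, pct_out, p_value,
#'   p_adj; sorted by cluster then decreasing fold change.
#' @export
deg <- function(nm, labels, min_pct = 0.1, logfc_threshold = 0.25) {
  labels <- labels[match(nm$barcodes, labels$barcode), ]
  clusters <- sort(unique(labels$cluster))
  assert_that(length(clusters) >= 2, "need at least 2 clusters")
  v <- nm$values
  expm1_v <- v
  expm1_v@x <- expm1(expm1_v@x)
  res <- purrr::map_dfr(clusters, function(cl) {
    inside <- labels$cluster == cl
    if (sum(inside) < 3) {
      warn(paste("cluster", cl, "has fewer than 3 spots; skipped"))
      return(NULL)
    }
    n_in <- sum(inside)
    n_out <- sum(!inside)
    pct_in <- Matrix::colSums(v[inside, , drop = FALSE] > 0) / n_in
    pct_out <- Matrix::colSums(v[!inside, , drop = FALSE] > 0) / n_out
    m_in <- Matrix::colMeans(expm1_v[inside, , drop = FALSE])
    m_out <- Matrix::colMeans(expm1_v[!inside, , drop = FALSE])
    lfc <- log2((m_in + 1) / (m_out + 1))
    keep <- which(pmax(pct_in, pct_out) >= min_pct &
                    abs(lfc) >= logfc_threshold)
    if (length(keep) == 0) return(NULL)
    pv <- vapply(keep, function(j) {
      col <- as.numeric(v[, j])
      suppressWarnings(wilcox.test(col[inside], col[!inside],
                                   exact = FALSE)$p.value)
    }, numeric(1))
    tibble::tibble(
      cluster = cl, gene = nm$genes[keep], avg_log2FC = lfc[keep],
      pct_in = pct_in[keep], pct_out = pct_out[keep], p_value = pv,
      p_adj = p.adjust(pv, method = "BH")
    )
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(cluster = integer(), gene = character(),
                          avg_log2FC = numeric(), pct_in = numeric(),
                          pct_out = numeric(), p_value = numeric(),
                          p_adj = numeric()))
  }
  dplyr::arrange(res, .data$cluster, dplyr::desc(.data$avg_log2FC))
}

#' Top-n marker signature for a cluster
#'
#' @param dt a [deg()] table.
#' @param cluster cluster id present in `dt`.
#' @param n number of genes (default 50); ties in `avg_log2FC` are broken by
#'   smaller p-value, then gene name.
#' @return A [gene_signature()].
#' @export
top_n_signature <- function(dt, cluster, n = 50) {
  rows <- dt[dt$cluster == cluster, ]
  assert_that(nrow(rows) > 0, paste("cluster", cluster, "not in DEG table"))
  rows <- dplyr::arrange(rows, dplyr::desc(.data$avg_log2FC),
                         .data$p_value, .data$gene)
  if (nrow(rows) < n) {
    warn(paste0("only ", nrow(rows), " genes available for cluster ",
                cluster, " (requested ", n, ")"))
  }
  top <- head(rows, n)
  gene_signature(paste0("cluster", cluster, "_top", nrow(top)), top$gene)
}
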