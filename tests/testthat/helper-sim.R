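# Shared fixtures built in code: a small simulated sample cached per
# (seed, pattern), plus constructors for hand-crafted matrices.

tiny_cfg <- function(seed = 1, pattern = "exclusion", ...) {
  sim_config(n_rows = 20, n_cols = 20, n_genes = 300, ring_width = 2,
             stroma_width = 1, pattern = pattern, seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

tiny_sim <- function(seed = 1, pattern = "exclusion") {
  key <- paste0("sim_", seed, "_", pattern)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_visium(tiny_cfg(seed, pattern))
  }
  .fixture_cache[[key]]
}

tiny_nm <- function(seed = 1, pattern = "exclusion") {
  key <- paste0("nm_", seed, "_", pattern)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- normalize_counts(tiny_sim(seed, pattern)$spots)
  }
  .fixture_cache[[key]]
}

# SpotMatrix from a bare counts matrix on a synthetic lattice
sm_from_counts <- function(counts, genes = NULL) {
  n <- nrow(counts)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(ncol(counts)))
  side <- ceiling(sqrt(n))
  rows <- (seq_len(n) - 1) %/% side
  cols <- (seq_len(n) - 1) %% side
  spot_matrix(counts, sprintf("s%03d", seq_len(n)), genes,
              data.frame(barcode = sprintf("s%03d", seq_len(n)),
                         in_tissue = 1L, array_row = rows, array_col = cols,
                         pxl_row = rows * 10, pxl_col = cols * 10))
}

nm_from_counts <- function(counts, scale_target = NULL, genes = NULL) {
  normalize_counts(sm_from_counts(counts, genes), scale_target)
}

# adjusted Rand index (independent contingency-table implementation)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# lattice spot data frame for boundary/classification tests
lattice_df <- function(n_rows, n_cols) {
  g <- expand.grid(array_row = seq_len(n_rows) - 1,
                   array_col = seq_len(n_cols) - 1)
  tibble::tibble(
    barcode = sprintf("b%03d", seq_len(nrow(g))),
    array_row = g$array_row, array_col = g$array_col
  )
}

# study-scale fixture (full default gene panel; what the recovery studies use)
mid_sim <- function(seed = 1, pattern = "exclusion") {
  key <- paste0("mid_", seed, "_", pattern)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_visium(
      sim_config(n_rows = 30, n_cols = 30, pattern = pattern, seed = seed))
  }
  .fixture_cache[[key]]
}
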