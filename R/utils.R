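# Internal helpers: seeding, assertions, small numeric utilities.

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats median p.adjust pchisq pnorm prcomp pt quantile rbinom
#'   rexp rgamma rlnorm rnbinom rnorm runif sd setNames var wilcox.test cor
#'   cutree dist hclust as.dist
#' @importFrom utils head
NULL

# Derive a stream-specific 32-bit seed from one master seed so that layout,
# counts, survival draws etc. are independently reproducible.
stream_seed <- function(seed, stream) {
  streams <- c(
    layout = 11L, counts = 23L, coloc = 37L, survival = 41L,
    ihc = 53L, cluster = 67L, perm = 79L, subsample = 97L
  )
  if (!stream %in% names(streams)) {
    abort(paste0("unknown RNG stream: ", stream))
  }
  s <- (as.numeric(seed) %% 1048573) * 2039 + streams[[stream]]
  as.integer(s %% 2147483647)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x == as.integer(x)
}

# Sparse column-operator for a centered moving average with shrinking edge
# windows over `n` ordered positions: smoothed = X %*% ma_operator(n, window).
ma_operator <- function(n, window) {
  assert_that(window >= 1 && window %% 2 == 1, "window must be odd and >= 1")
  half <- (window - 1L) / 2L
  j <- rep.int(seq_len(n), times = pmin(seq_len(n) + half, n) -
                 pmax(seq_len(n) - half, 1L) + 1L)
  i <- unlist(lapply(seq_len(n), function(k) {
    seq.int(max(1L, k - half), min(n, k + half))
  }), use.names = FALSE)
  w <- 1 / tabulate(j, nbins = n)[j]
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n))
}
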