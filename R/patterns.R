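# Tumor-boundary extraction, immune-activation vs immune-exclusion
# classification, and spot-level signature co-localization.

neighbor_offsets <- function(neighborhood) {
  four <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  if (neighborhood == 4) return(four)
  # hex-like 6-neighborhood on the square embedding (adds one diagonal axis)
  rbind(four, cbind(c(-1, 1), c(1, -1)))
}

# indices of lattice neighbors for every spot (list of integer vectors)
lattice_neighbors <- function(array_row, array_col, neighborhood = 4) {
  off <- neighbor_offsets(neighborhood)
  key <- paste(array_row, array_col, sep = "_")
  lookup <- setNames(seq_along(key), key)
  lapply(seq_along(key), function(i) {
    cand <- paste(array_row[i] + off[, 1], array_col[i] + off[, 2], sep = "_")
    unname(lookup[cand[cand %in% names(lookup)]])
  })
}

#' Extract the tumor boundary rings
#'
#' The boundary consists of two lattice-adjacency rings: the inner ring
#' (malignant spots adjacent to at least one non-malignant spot) and the
#' outer ring (non-malignant spots adjacent to at least one malignant spot).
#'
#' @param spot_df data frame with columns `barcode`, `array_row`,
#'   `array_col` and logical `malignant`.
#' @param neighborhood 4 (default) or 6 lattice adjacency.
#' @return tibble (barcode, ring) with `ring` in `{"inner", "outer"}`;
#'   empty when there are no malignant spots.
#' @export
tumor_boundary <- function(spot_df, neighborhood = 4) {
  need <- c("barcode", "array_row", "array_col", "malignant")
  assert_that(all(need %in% names(spot_df)),
              "spot_df needs barcode, array_row, array_col, malignant")
  mal <- spot_df$malignant
  if (!any(mal)) {
    return(tibble::tibble(barcode = character(), ring = character()))
  }
  nb <- lattice_neighbors(spot_df$array_row, spot_df$array_col, neighborhood)
  touches_nonmal <- vapply(nb, function(j) any(!mal[j]), logical(1))
  touches_mal <- vapply(nb, function(j) any(mal[j]), logical(1))
  inner <- mal & touches_nonmal
  outer <- !mal & touches_mal
  tibble::tibble(
    barcode = c(spot_df$barcode[inner], spot_df$barcode[outer]),
    ring = c(rep("inner", sum(inner)), rep("outer", sum(outer)))
  )
}

# Malignant area with enclosed holes filled: non-malignant spots that cannot
# reach the lattice hull through non-malignant 4-neighbor paths belong to the
# tumor area (they are e.g. intra-tumor immune aggregates).
tumor_area <- function(spot_df, neighborhood = 4) {
  mal <- spot_df$malignant
  nb <- lattice_neighbors(spot_df$array_row, spot_df$array_col, neighborhood)
  on_hull <- spot_df$array_row %in% range(spot_df$array_row) |
    spot_df$array_col %in% range(spot_df$array_col)
  outside <- rep(FALSE, nrow(spot_df))
  queue <- which(on_hull & !mal)
  outside[queue] <- TRUE
  while (length(queue) > 0) {
    nxt <- unique(unlist(nb[queue], use.names = FALSE))
    nxt <- nxt[!outside[nxt] & !mal[nxt]]
    outside[nxt] <- TRUE
    queue <- nxt
  }
  mal | (!outside)
}

#' Classify a sample as immune activation or immune exclusion
#'
#' Computes the sample-wide `q`-th percentile of the immune score, takes the
#' interior of the malignant area (the malignant spots plus any enclosed
#' non-malignant spots, minus the inner boundary ring) and measures
#' `f_intra`, the fraction of interior spots scoring above the percentile.
#' The sample is called `"activation"` when `f_intra >= f_min`, otherwise
#' `"exclusion"`. `f_boundary` reports the same fraction among the boundary
#' rings.
#'
#' @param spot_df data frame with columns `barcode`, `array_row`,
#'   `array_col`, logical `malignant` and numeric `immune_score`.
#' @param q percentile (0-100) of the sample-wide immune score (default 75).
#' @param f_min minimum interior high-immune fraction for an activation
#'   call (default 0.10).
#' @param neighborhood lattice adjacency (default 4).
#' @return One-row tibble of class `tme_pattern`: pattern, f_intra,
#'   f_boundary, q, f_min, cutoff, n_interior, n_boundary.
#' @export
classify_infiltration <- function(spot_df, q = 75, f_min = 0.10,
                                  neighborhood = 4) {
  need <- c("barcode", "array_row", "array_col", "malignant", "immune_score")
  assert_that(all(need %in% names(spot_df)),
              "spot_df needs barcode, coordinates, malignant, immune_score")
  assert_that(any(spot_df$malignant), "no malignant spots")
  assert_that(q > 0 && q < 100, "q must be a percentile in (0, 100)")
  area <- tumor_area(spot_df, neighborhood)
  area_df <- spot_df
  area_df$malignant <- area
  rings <- tumor_boundary(area_df, neighborhood)
  interior <- area & !(spot_df$barcode %in% rings$barcode[rings$ring == "inner"])
  if (!any(interior)) {
    abort(paste("zero interior malignant spots; the tumor area is all",
                "boundary - review the sample or reduce the ring"))
  }
  cutoff <- quantile(spot_df$immune_score, q / 100, names = FALSE)
  boundary_b <- tumor_boundary(spot_df, neighborhood)$barcode
  f_intra <- mean(spot_df$immune_score[interior] > cutoff)
  f_boundary <- if (length(boundary_b) > 0) {
    mean(spot_df$immune_score[spot_df$barcode %in% boundary_b] > cutoff)
  } else {
    NA_real_
  }
  structure(tibble::tibble(
    pattern = if (f_intra >= f_min) "activation" else "exclusion",
    f_intra = f_intra, f_boundary = f_boundary, q = q, f_min = f_min,
    cutoff = cutoff, n_interior = sum(interior),
    n_boundary = length(boundary_b)
  ), class = c("tme_pattern", class(tibble::tibble())))
}

# all permutations of 1..n as an n!-row matrix (used by the exact
# co-localization test at small n)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spot-level co-localization of two scores
#'
#' Spearman correlation with tie-corrected (mid-rank) handling. The
#' two-sided p-value uses the t approximation, or the exact permutation
#' distribution when `n <= 10`.
#'
#' @param df data frame holding both score columns (pre-filter it to the
#'   spot subset of interest: all spots, intra-tumor spots, immune-cluster
#'   spots, ...).
#' @param a,b column names (tidy-eval) of the two scores.
#' @return One-row tibble: rho, p_value, n_spots, method.
#' @export
colocalization <- function(df, a, b) {
  x <- dplyr::pull(df, {{ a }})
  y <- dplyr::pull(df, {{ b }})
  n <- length(x)
  assert_that(n >= 3, "need at least 3 spots")
  assert_that(sd(x) > 0 && sd(y) > 0,
              "co-localization undefined for a constant score")
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 10) {
    perms <- all_perms(n)
    ry_mat <- matrix(ry[perms], nrow(perms))
    s <- as.vector(ry_mat %*% rx)
    rho_perm <- (s - n * mean(rx) * mean(ry)) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = min(1, p), n_spots = n,
                 method = method)
}

#' Assemble and write the per-sample pattern report
#'
#' @param spot_df per-spot annotation table (barcode, coordinates, cluster,
#'   cnv columns, scores, ...).
#' @param pattern a [classify_infiltration()] result.
#' @param out_dir directory for `spot_annotations.tsv` and `summary.json`;
#'   `NULL` skips writing.
#' @return list with `spots` (the annotation tibble, one row per spot) and
#'   `summary` (named list mirrored to JSON); file output is byte-stable for
#'   identical inputs.
#' @export
pattern_report <- function(spot_df, pattern, out_dir = NULL) {
  summary <- c(as.list(pattern),
               list(n_spots = nrow(spot_df),
                    n_malignant = sum(spot_df$malignant)))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(spot_df, file.path(out_dir, "spot_annotations.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(spots = tibble::as_tibble(spot_df), summary = summary)
}
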