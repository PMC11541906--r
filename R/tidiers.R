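# broom-style tidiers for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn optimal_cutpoint tidy(): one row per group with record and
#'   event counts.
#' @param x a `cutpoint_fit`.
#' @param ... unused.
#' @method tidy cutpoint_fit
#' @export
tidy.cutpoint_fit <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$data, .data$group),
    n = dplyr::n(), events = sum(.data$event),
    median_time = median(.data$time), .groups = "drop"
  )
}

#' @describeIn optimal_cutpoint glance(): one-row fit summary.
#' @method glance cutpoint_fit
#' @export
glance.cutpoint_fit <- function(x, ...) {
  tibble::tibble(cutpoint = x$cutpoint, statistic = x$statistic,
                 p_value = x$p_value, n = nrow(x$data), var = x$var)
}

#' @describeIn run_pipeline tidy(): the per-spot annotation tibble.
#' @param x a `tme_run`.
#' @param ... unused.
#' @method tidy tme_run
#' @export
tidy.tme_run <- function(x, ...) x$scores

#' @describeIn run_pipeline glance(): one-row sample summary (pattern call,
#'   fractions, counts).
#' @method glance tme_run
#' @export
glance.tme_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$pattern),
    tibble::tibble(n_spots = nrow(x$scores),
                   n_malignant = sum(x$scores$malignant),
                   n_clusters = length(unique(x$clusters$cluster)),
                   reference_cluster = x$reference_cluster)
  )
}

#' @describeIn infer_cnv tidy(): the per-spot CNV calls.
#' @param x a `cnv_result`.
#' @param ... unused.
#' @method tidy cnv_result
#' @export
tidy.cnv_result <- function(x, ...) x$spot_calls

#' @describeIn infer_cnv glance(): per-cluster CNV scores and malignant
#'   flags.
#' @method glance cnv_result
#' @export
glance.cnv_result <- function(x, ...) x$clusters
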