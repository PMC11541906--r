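# ggplot2 views of the result types.

#' @importFrom ggplot2 ggplot aes geom_tile geom_step geom_col geom_point
#'   scale_fill_viridis_c coord_equal labs facet_wrap theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Lattice map of a per-spot variable
#'
#' @param spot_df data frame with `array_row`, `array_col` and the fill
#'   variable.
#' @param fill column (tidy-eval) to map to fill.
#' @return A ggplot.
#' @export
plot_spot_map <- function(spot_df, fill) {
  ggplot(spot_df, aes(x = .data$array_col, y = .data$array_row,
                      fill = {{ fill }})) +
    geom_tile() +
    coord_equal() +
    theme_minimal() +
    labs(x = NULL, y = NULL)
}

#' @describeIn run_pipeline autoplot(): immune-score map with the malignant
#'   area outlined by the boundary rings.
#' @param object a `tme_run`.
#' @method autoplot tme_run
#' @export
autoplot.tme_run <- function(object, ...) {
  df <- object$scores
  plot_spot_map(df, .data$immune_score) +
    scale_fill_viridis_c() +
    geom_point(data = df[!is.na(df$boundary_ring), ],
               aes(x = .data$array_col, y = .data$array_row),
               inherit.aes = FALSE, shape = 0, size = 0.8,
               colour = "red") +
    labs(title = paste("immune score;", object$pattern$pattern),
         fill = "immune\nscore")
}

#' Kaplan-Meier step plot
#'
#' @param km a [km_estimate()] tibble, optionally with a `group` column
#'   (bind rows of per-group estimates).
#' @return A ggplot.
#' @export
plot_km <- function(km) {
  p <- if ("group" %in% names(km)) {
    ggplot(km, aes(x = .data$time, y = .data$survival,
                   colour = .data$group))
  } else {
    ggplot(km, aes(x = .data$time, y = .data$survival))
  }
  p + geom_step() + theme_minimal() +
    labs(y = "survival probability", x = "time")
}

#' @describeIn optimal_cutpoint autoplot(): Kaplan-Meier curves of the two
#'   groups defined by the fitted cutpoint.
#' @param object a `cutpoint_fit`.
#' @method autoplot cutpoint_fit
#' @export
autoplot.cutpoint_fit <- function(object, ...) {
  km <- dplyr::bind_rows(lapply(split(object$data, object$data$group),
                                km_estimate), .id = "group")
  plot_km(km) +
    labs(title = paste0(object$var, " cutpoint ",
                        format(object$cutpoint, digits = 3),
                        " (log-rank p = ",
                        format(object$p_value, digits = 3), ")"))
}

#' Outgoing vs incoming signaling roles
#'
#' @param roles a [signaling_roles()] tibble.
#' @return A ggplot scatter of outgoing vs incoming totals per cluster.
#' @export
plot_signaling_roles <- function(roles) {
  ggplot(roles, aes(x = .data$outgoing, y = .data$incoming)) +
    geom_point() +
    ggplot2::geom_text(aes(label = .data$cluster), vjust = -0.6,
                       size = 3) +
    theme_minimal() +
    labs(x = "outgoing interaction strength",
         y = "incoming interaction strength")
}

#' Ligand-receptor interaction bubble plot
#'
#' @param interactions an [lr_permutation_test()] tibble.
#' @param alpha interactions with `p_value > alpha` are dropped (when a
#'   p_value column is present).
#' @return A ggplot bubble chart: sender -> receiver vs ligand-receptor
#'   pair, sized by score.
#' @export
plot_interaction_bubbles <- function(interactions, alpha = 0.05) {
  df <- interactions
  if ("p_value" %in% names(df)) df <- df[df$p_value <= alpha, ]
  df$pair <- paste(df$ligand, df$receptor, sep = " -> ")
  df$edge <- paste(df$sender, df$receiver, sep = " -> ")
  ggplot(df, aes(x = .data$edge, y = .data$pair, size = .data$score)) +
    geom_point() +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    labs(x = "sender -> receiver", y = NULL)
}
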