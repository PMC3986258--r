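# ggplot2 visualizations for each result type.

#' Plot the feature importance ranking
#'
#' Dot-and-error-bar chart of the overall permutation importance of the 11
#' features, ordered by rank.
#'
#' @param object A `mito_importance` tibble from [importance_ranking()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mito_importance
#' @export
autoplot.mito_importance <- function(object, ...) {
  df <- dplyr::mutate(object,
                      feature = stats::reorder(.data$feature,
                                               .data$importance_all))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance_all,
                                   y = .data$feature)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$importance_all - .data$sd_all,
      xmax = .data$importance_all + .data$sd_all)) +
    ggplot2::labs(x = "increase in OOB error when permuted", y = NULL,
                  title = "Feature importance") +
    ggplot2::theme_minimal()
}

#' Plot class error against forest size
#'
#' @param curve Tibble from [class_error_curve()].
#' @return A ggplot.
#' @export
plot_error_curve <- function(curve) {
  df <- tidyr::pivot_longer(curve, c("fission_error", "fusion_error"),
                            names_to = "class", values_to = "error")
  df$class <- sub("_error", "", df$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_trees, y = .data$error,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(fission = "#3366cc",
                                            fusion = "#cc3333")) +
    ggplot2::labs(x = "number of trees", y = "OOB class error") +
    ggplot2::theme_minimal()
}

#' Plot normalized pre-event morphology traces
#'
#' Mean P/P0 and S/S0 against time before the event, with a shaded
#' standard-error ribbon, split by event type.
#'
#' @param object A `mito_traces` from [pre_event_traces()].
#' @param frame_interval_s Seconds per frame used for the time axis.
#'   Default 5.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mito_traces
#' @export
autoplot.mito_traces <- function(object, frame_interval_s = 5, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            c("mean_P_ratio", "mean_S_ratio"),
                            names_to = "measure", values_to = "mean")
  df$se <- ifelse(df$measure == "mean_P_ratio", df$se_P, df$se_S)
  df$measure <- ifelse(df$measure == "mean_P_ratio", "P/P0", "S/S0")
  df$time_s <- -df$offset * frame_interval_s
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                   colour = .data$call, fill = .data$call)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(fission = "#3366cc",
                                            fusion = "#cc3333")) +
    ggplot2::scale_fill_manual(values = c(fission = "#3366cc",
                                          fusion = "#cc3333")) +
    ggplot2::labs(x = "time before event (s)", y = "normalized value") +
    ggplot2::theme_minimal()
}

#' Show a labeled segmentation frame
#'
#' @param labels Integer label matrix.
#' @return A ggplot raster of the labels (random hues, background white).
#' @export
plot_labels <- function(labels) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(labels)), times = ncol(labels)),
    col = rep(seq_len(ncol(labels)), each = nrow(labels)),
    label = as.vector(labels))
  df <- dplyr::filter(df, .data$label > 0L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
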