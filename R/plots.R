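#' Plot joint-angle traces
#'
#' One panel per joint, left and right limbs overlaid -- the quickest visual
#' check that trimming and angle extraction behaved.
#'
#' @param angles Per-frame angle tibble from [compute_angle_traces()].
#' @return A ggplot object.
#' @export
plot_angle_traces <- function(angles) {
  long <- angles |>
    tidyr::pivot_longer(dplyr::all_of(ANGLE_NAMES),
                        names_to = c("joint", "side"), names_sep = "_",
                        values_to = "degrees")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$frame, y = .data$degrees,
                               colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~joint, scales = "free_y") +
    ggplot2::labs(x = "frame", y = "angle (degrees)", colour = "limb") +
    ggplot2::theme_minimal()
}

#' Histogram of prediction minus reference score
#'
#' Mirrors the usual presentation of network-vs-assessor difference
#' distributions: a bar per signed difference, optionally faceted by a
#' grouping column such as `network` or `seen_flag`.
#'
#' @param predictions Tibble with `predicted` and `median_score` columns.
#' @param by Optional name of a column to facet by.
#' @return A ggplot object.
#' @export
plot_difference_histogram <- function(predictions, by = NULL) {
  d <- dplyr::mutate(predictions,
                     diff = .data$predicted - .data$median_score)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::scale_x_continuous(breaks = -4:4, limits = c(-4.5, 4.5)) +
    ggplot2::labs(x = "predicted - median assessor score", y = "trials") +
    ggplot2::theme_minimal()
  if (!is.null(by)) p <- p + ggplot2::facet_wrap(by)
  p
}

#' @method autoplot nested_cv
#' @export
autoplot.nested_cv <- function(object, ...) {
  plot_difference_histogram(object$predictions)
}

#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$diff_tally,
                  ggplot2::aes(x = .data$abs_diff, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "|predicted - reference|", y = "trials") +
    ggplot2::theme_minimal()
}

#' @method autoplot arm_rf
#' @export
autoplot.arm_rf <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$feature,
                                                     .data$importance),
                                  y = .data$importance)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized importance") +
    ggplot2::theme_minimal()
}
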