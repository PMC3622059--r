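#' Plot channel traces
#'
#' One line per ROI, one panel per excitation channel.
#'
#' @param traces A trace tibble from [extract_traces()].
#' @param normalize Plot delta-F/F relative to the first sample instead of
#'   raw counts.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, normalize = FALSE) {
  if (normalize) {
    traces <- dplyr::mutate(
      dplyr::group_by(traces, .data$roi_id, .data$channel),
      value = (.data$value - .data$value[1]) / .data$value[1]
    )
  }
  ggplot2::ggplot(traces, ggplot2::aes(.data$time_s / 60, .data$value,
                                       colour = factor(.data$roi_id))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (min)",
                  y = if (normalize) expression(Delta * F / F) else
                    "background-subtracted counts",
                  colour = "ROI") +
    ggplot2::theme_minimal()
}

#' Plot ratio traces
#'
#' @param ratios A ratio tibble from [pair_ratio()].
#' @return A ggplot object.
#' @export
plot_ratio <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(.data$time_s / 60, .data$r,
                                       colour = factor(.data$roi_id))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = expression(R[430 / 500]),
                  colour = "ROI") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted dose-response curve
#'
#' Fitted 4-parameter logistic with the underlying calibration points on a
#' log chloride axis.
#'
#' @param object A `dose_response` object from [fit_dose_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_response <- function(object, ...) {
  grid <- tibble::tibble(
    cl_mM = 10^seq(log10(min(object$points$cl_mM)),
                   log10(max(object$points$cl_mM)), length.out = 200)
  )
  grid$r <- predict(object, grid$cl_mM)
  ggplot2::ggplot(object$points, ggplot2::aes(.data$cl_mM, .data$r)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[Cl-]i (mM)", y = expression(R[430 / 500])) +
    ggplot2::theme_minimal()
}
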