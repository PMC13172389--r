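#' Plot Kaplan-Meier curves
#'
#' Step survival curves per group from a [km_estimate()] table.
#'
#' @param km A `pkip_km` tibble.
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  start <- km %>%
    group_by(.data$group) %>%
    summarise(time = 0, survival = 1, .groups = "drop")
  ggplot2::ggplot(bind_rows(start, km),
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Hours since presentation",
                  y = "Survival probability", colour = "Group") +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' Mean predicted probability against observed event rate per bin, with the
#' identity line.
#'
#' @param x A `pkip_cv` object or a calibration table from [calibration()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(x) {
  tab <- if (inherits(x, "pkip_cv")) x$calibration else x
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_pred,
                                    y = .data$obs_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed event rate", size = "n") +
    ggplot2::theme_minimal()
}

#' Forest plot of hazard ratios
#'
#' @param hr A `pkip_hr` tibble from [hazard_ratios_vs_reference()].
#' @return A ggplot object.
#' @export
plot_forest <- function(hr) {
  hr$group <- factor(hr$group, levels = rev(hr$group))
  ggplot2::ggplot(hr, ggplot2::aes(x = .data$hr, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi),
                            height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_calibration
#' @param object A `pkip_cv` object.
#' @param ... Unused.
#' @export
autoplot.pkip_cv <- function(object, ...) {
  plot_calibration(object)
}

#' @rdname plot_km
#' @param object A `pkip_km` tibble.
#' @param ... Unused.
#' @export
autoplot.pkip_km <- function(object, ...) {
  plot_km(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
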