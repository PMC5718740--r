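#' Plot a DVH
#'
#' Cumulative (default) or differential dose-volume histogram.
#'
#' @param object A [analytic_dvh()] result.
#' @param cumulative Plot the cumulative DVH (default) or the differential
#'   histogram.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dvh <- function(object, cumulative = TRUE, ...) {
  if (cumulative) {
    cum <- cumulative_dvh(object)
    ggplot2::ggplot(cum, ggplot2::aes(x = .data$dose_gy,
                                      y = 100 * .data$volume_fraction_ge)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Total dose (Gy)", y = "PTV volume ≥ dose (%)")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy,
                                         y = 100 * .data$volume_fraction)) +
      ggplot2::geom_col(width = attr(object, "bin_width_gy") %||% 0.5) +
      ggplot2::labs(x = "Total dose (Gy)", y = "PTV volume per bin (%)")
  }
}

#' Plot a radial dose profile
#'
#' Monte Carlo dose versus distance with one-standard-deviation error bars,
#' normalised to the first point.
#'
#' @param object A [radial_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_profile <- function(object, ...) {
  d0 <- object$dose[1]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance_cm, y = .data$dose / d0)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = (.data$dose - .data$dose * .data$rel_unc) / d0,
      ymax = (.data$dose + .data$dose * .data$rel_unc) / d0)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from source (cm)", y = "Relative dose")
}

#' Plot TCP against a perturbation variable
#'
#' @param object A [combined_tcp()] result.
#' @param x Name of the column to use on the x axis (default picks the
#'   perturbation column with more than one value).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcp_table <- function(object, x = NULL, ...) {
  if (is.null(x)) {
    cand <- c("concentration_pct", "shift_mm", "deformation_mm",
              "diameter_cm")
    nv <- vapply(cand, function(v) length(unique(object[[v]])), integer(1))
    x <- cand[which.max(nv)]
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[x]], y = .data$tcp_pct,
                               colour = factor(.data$diameter_cm))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = x, y = "TCP (%)", colour = "Balloon (cm)")
}
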