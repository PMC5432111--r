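#' Plot a dilution curve
#'
#' Apparent growth rate against dilution fraction, with the fitted OLS line.
#' The intercept of the line estimates phytoplankton growth; its negative
#' slope estimates grazing mortality.
#'
#' @param object A `dilution_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dilution_curve <- function(object, ...) {
  fit <- fit_dilution_curve(object)
  lab <- sprintf("mortality estimate = %.3g /day, growth estimate = %.3g /day",
                 fit$mortality_estimate, fit$growth_estimate)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$F, y = .data$r_tilde)) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Fraction of whole seawater, F",
                  y = expression(Apparent~growth~rate~tilde(r)~(day^-1)),
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot estimator bias across the grazing-pressure gradient
#'
#' Mortality-rate bias (estimate / true rate) against grazing pressure
#' delta_Z for each assessed method, with reference bands at +/-10% and
#' +/-25% around unbiased estimation.
#'
#' @param object A `pressure_sweep` tibble from [sweep_grazing_pressure()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pressure_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_Z, y = .data$bias,
                                       colour = .data$method)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0.75, ymax = 1.25,
                      alpha = 0.08, fill = "grey30") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0.9, ymax = 1.1,
                      alpha = 0.15, fill = "grey30") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Grazing~pressure~delta[Z]),
                  y = "Mortality rate bias (estimate / true)",
                  colour = "Method") +
    ggplot2::theme_minimal()
}
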