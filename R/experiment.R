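#' Dilution experiment design
#'
#' Describes one in-silico dilution experiment: which quantities are diluted,
#' the dilution fractions, the incubation length and the initial whole
#' seawater phytoplankton density.
#'
#' @param method `"classical"` dilutes both phytoplankton and grazers
#'   (bottle at fraction F starts at F P0, F Z0); `"z-dilution"` dilutes the
#'   grazers only (P0, F Z0).
#' @param fractions Strictly increasing dilution fractions in (0, 1], at
#'   least two. Default is the standard 10-bottle series F = 0.1, ..., 1.
#' @param incubation Incubation time, days. Default 1 (a 24 h incubation).
#' @param P0 Either the sentinel `"steady-state"` (default), resolving at
#'   build time to the grazed steady state K (1 - a Z0 / r), or a positive
#'   numeric density in cells ml^-1.
#' @return An object of class `experiment_design`.
#' @examples
#' experiment_design("z-dilution")
#' @export
experiment_design <- function(method = c("classical", "z-dilution"),
                              fractions = seq(0.1, 1, by = 0.1),
                              incubation = 1,
                              P0 = "steady-state") {
  method <- match.arg(method)
  if (length(fractions) < 2) abort("`fractions` needs at least two dilution levels.")
  if (any(fractions <= 0 | fractions > 1)) abort("`fractions` must lie in (0, 1].")
  if (any(diff(fractions) <= 0)) abort("`fractions` must be strictly increasing.")
  if (!(is.numeric(incubation) && length(incubation) == 1 && incubation > 0)) {
    abort("`incubation` must be a single positive number of days.")
  }
  if (is.character(P0)) {
    if (!identical(P0, "steady-state")) {
      abort('`P0` must be a positive density or the sentinel "steady-state".')
    }
  } else if (!(is.numeric(P0) && length(P0) == 1 && is.finite(P0) && P0 > 0)) {
    abort('`P0` must be a positive density or the sentinel "steady-state".')
  }
  structure(list(method = method, fractions = as.numeric(fractions),
                 incubation = incubation, P0 = P0),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n")
  cat(sprintf("  method:     %s\n  fractions:  %s\n  incubation: %g day(s)\n  P0:         %s\n",
              x$method, paste(signif(x$fractions, 4), collapse = ", "),
              x$incubation,
              if (is.character(x$P0)) x$P0 else format(x$P0)))
  invisible(x)
}

# resolve the initial whole-seawater density, enforcing the steady-state regime
resolve_P0 <- function(design, params) {
  if (is.character(design$P0)) {
    if (grazing_pressure(params) >= 1) {
      abort(paste0("Invalid regime: steady-state initialisation requires grazing ",
                   "pressure delta_Z < 1 (got ", grazing_pressure(params), ")."))
    }
    steady_state_density(params)
  } else {
    design$P0
  }
}

#' Build the bottle series for a dilution experiment
#'
#' Expands a design into one bottle per dilution fraction. Classical bottles
#' at fraction F contain phytoplankton F P0 and grazers F Z0; Z-dilution
#' bottles keep phytoplankton at ambient density P0 and dilute only the
#' grazers to F Z0.
#'
#' @param design An [experiment_design()].
#' @param params An [ecosystem_params()] object.
#' @return A tibble of class `dilution_series` with columns `F`, `P_init`
#'   and `Z`, carrying the design and parameters as attributes.
#' @examples
#' dilution_series(experiment_design(), scenario_params("high"))
#' @export
dilution_series <- function(design, params) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "ecosystem_params"))
  P0 <- resolve_P0(design, params)
  f <- design$fractions
  out <- tibble(
    F = f,
    P_init = if (design$method == "classical") f * P0 else rep(P0, length(f)),
    Z = f * params$Z0
  )
  structure(out, design = design, params = params,
            class = c("dilution_series", class(out)))
}

#' Apparent growth rate from two density measurements
#'
#' The net per-capita rate realised over an incubation:
#' r~ = (1/T) ln(P_end / P_start). This is the quantity plotted against the
#' dilution fraction to form the dilution curve.
#'
#' @param P_start,P_end Phytoplankton densities at the start and end of the
#'   incubation, cells ml^-1 (positive; vectorised).
#' @param T Incubation time, days (positive).
#' @return Rate(s), day^-1.
#' @examples
#' apparent_growth_rate(1e6, 1e6 * exp(0.5), T = 1)  # 0.5
#' @export
apparent_growth_rate <- function(P_start, P_end, T) {
  if (any(!is.finite(P_start)) || any(P_start <= 0) ||
      any(!is.finite(P_end)) || any(P_end <= 0)) {
    abort("Densities must be positive and finite.")
  }
  if (any(T <= 0)) abort("`T` must be positive.")
  log(P_end / P_start) / T
}

#' Incubate a bottle series and record the dilution curve
#'
#' Advances each bottle for the design's incubation time under the stated
#' model (grazers constant within each bottle) and computes the apparent
#' growth rate from the start and end densities.
#'
#' @param series A [dilution_series()] tibble.
#' @param model `"logistic"` or `"exponential"`.
#' @return A tibble of class `dilution_curve` with columns `F`, `P_init`,
#'   `Z`, `P_final` and `r_tilde`.
#' @export
simulate_incubation <- function(series, model = c("logistic", "exponential")) {
  stopifnot(inherits(series, "dilution_series"))
  model <- match.arg(model)
  design <- attr(series, "design")
  params <- attr(series, "params")
  T <- design$incubation
  P_final <- solve_bottle(series$P_init, series$Z, params, model, t = T)
  out <- tibble(
    F = series$F, P_init = series$P_init, Z = series$Z, P_final = P_final,
    r_tilde = apparent_growth_rate(series$P_init, P_final, T)
  )
  structure(out, design = design, params = params, model = model,
            class = c("dilution_curve", class(out)))
}

#' Run one in-silico dilution experiment
#'
#' Convenience pipeline: builds the bottle series for a design and simulates
#' the incubation, returning the dilution curve. Deterministic — one bottle
#' per dilution level, no replicates, no measurement noise.
#'
#' @inheritParams dilution_series
#' @inheritParams simulate_incubation
#' @return A `dilution_curve` tibble (see [simulate_incubation()]).
#' @examples
#' run_dilution_experiment(experiment_design(), scenario_params("low"))
#' @export
run_dilution_experiment <- function(design, params,
                                    model = c("logistic", "exponential")) {
  simulate_incubation(dilution_series(design, params), model = model)
}

#' Fit the dilution-curve regression
#'
#' Ordinary least squares of the apparent growth rate on the dilution
#' fraction F. The intercept is read as the phytoplankton growth rate and
#' the negative of the slope as the grazing mortality estimate.
#'
#' @param curve A data frame with columns `F` and `r_tilde`, typically a
#'   `dilution_curve` from [run_dilution_experiment()].
#' @return An object of class `dilution_fit` with elements `slope`,
#'   `intercept`, `growth_estimate` (= intercept), `mortality_estimate`
#'   (= -slope), `r_squared` and the underlying `lm` fit. Supports
#'   [tidy()], [glance()] and `print()`.
#' @examples
#' scenario_params("high") |>
#'   (\(p) run_dilution_experiment(experiment_design(), p))() |>
#'   fit_dilution_curve()
#' @export
fit_dilution_curve <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("F", "r_tilde") %in% names(curve)))
  if (length(unique(curve$F)) < 2) {
    abort("Degenerate design: at least two distinct dilution fractions are required.")
  }
  if (any(!is.finite(curve$r_tilde))) abort("Non-finite apparent growth rates.")
  fit <- lm(r_tilde ~ F, data = curve)
  slope <- unname(coef(fit)[["F"]])
  intercept <- unname(coef(fit)[["(Intercept)"]])
  structure(list(
    slope = slope,
    intercept = intercept,
    growth_estimate = intercept,
    mortality_estimate = -slope,
    # exact model curves give machine-perfect fits; summary.lm warns about
    # those, but here they are the expected behaviour
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = nrow(curve),
    fit = fit,
    design = attr(curve, "design"),
    params = attr(curve, "params"),
    model = attr(curve, "model")
  ), class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat("<dilution_fit>  r_tilde ~ F (ordinary least squares)\n")
  cat(sprintf("  growth estimate (intercept): %.6g day^-1\n", x$growth_estimate))
  cat(sprintf("  mortality estimate (-slope): %.6g day^-1\n", x$mortality_estimate))
  cat(sprintf("  R-squared: %.6g   (n = %d bottles)\n", x$r_squared, x$n))
  invisible(x)
}
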