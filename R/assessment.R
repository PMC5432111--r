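#' Assess a dilution method against the true grazing rate
#'
#' Runs one dilution experiment, fits the dilution-curve regression and
#' compares the mortality estimate with the baseline grazing mortality
#' m = a Z0. The bias is the estimate divided by the baseline; values above
#' 1 mean the method overestimates grazing.
#'
#' @param design An [experiment_design()].
#' @param params An [ecosystem_params()] with a Z0 > 0 (bias is undefined
#'   without grazing).
#' @param model `"logistic"` or `"exponential"`.
#' @return A one-row tibble of class `dilution_assessment` with columns
#'   `method`, `model`, `delta_Z`, `baseline_mortality`,
#'   `growth_estimate`, `mortality_estimate`, `bias` and `percent_error`
#'   (= 100 (bias - 1)); the design, parameters and model are kept as
#'   attributes for provenance checks.
#' @examples
#' assess_method(experiment_design("classical"), scenario_params("low"))
#' @export
assess_method <- function(design, params, model = c("logistic", "exponential")) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(params, "ecosystem_params"))
  model <- match.arg(model)
  m <- baseline_mortality(params)
  if (m <= 0) abort("Bias is undefined when a * Z0 = 0 (no grazing).")
  est <- fit_dilution_curve(run_dilution_experiment(design, params, model))
  out <- tibble(
    method = design$method,
    model = model,
    delta_Z = grazing_pressure(params),
    baseline_mortality = m,
    growth_estimate = est$growth_estimate,
    mortality_estimate = est$mortality_estimate,
    bias = est$mortality_estimate / m,
    percent_error = 100 * (est$mortality_estimate - m) / m
  )
  structure(out, design = design, params = params, model = model,
            class = c("dilution_assessment", class(out)))
}

#' Sweep estimator bias across a gradient of grazing pressure
#'
#' Evaluates the dilution methods over a grid of grazing pressures delta_Z.
#' Each grid point keeps r, K and a fixed and sets the ambient grazer
#' density to Z0 = delta_Z r / a, with bottles initialised from the grazed
#' steady state P* = K (1 - delta_Z).
#'
#' @param delta_Z Strictly increasing grazing pressures, all in (0, 1).
#' @param params Base [ecosystem_params()] supplying r, K and a (its Z0 is
#'   ignored and recomputed per grid point).
#' @param methods Character vector of designs to assess, a subset of
#'   `c("classical", "z-dilution")`.
#' @param incubation Incubation time, days.
#' @param fractions Dilution fractions passed to [experiment_design()].
#' @param model `"logistic"` or `"exponential"`.
#' @return A tibble of class `pressure_sweep`: one `dilution_assessment`
#'   row per (grid point, method), ordered by `delta_Z` then `method`.
#' @examples
#' sweep_grazing_pressure(c(0.048, 0.48, 0.96), scenario_params("high"))
#' @export
sweep_grazing_pressure <- function(delta_Z,
                                   params = ecosystem_params(Z0 = 0),
                                   methods = c("classical", "z-dilution"),
                                   incubation = 1,
                                   fractions = seq(0.1, 1, by = 0.1),
                                   model = c("logistic", "exponential")) {
  stopifnot(inherits(params, "ecosystem_params"))
  model <- match.arg(model)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(delta_Z) < 1 || any(delta_Z <= 0 | delta_Z >= 1)) {
    abort("`delta_Z` values must lie strictly inside (0, 1).")
  }
  if (any(diff(delta_Z) <= 0)) abort("`delta_Z` must be strictly increasing.")
  if (params$a <= 0) abort("`params$a` must be positive to parameterise the sweep.")
  grid <- expand.grid(method = methods, delta_Z = delta_Z,
                      stringsAsFactors = FALSE)
  out <- purrr::pmap(grid, function(method, delta_Z) {
    p <- ecosystem_params(r = params$r, K = params$K, a = params$a,
                          Z0 = delta_Z * params$r / params$a)
    assess_method(experiment_design(method, fractions = fractions,
                                    incubation = incubation),
                  p, model = model)
  })
  out <- dplyr::arrange(dplyr::bind_rows(out), .data$delta_Z, .data$method)
  structure(out, incubation = incubation, model = model,
            base_params = params,
            class = c("pressure_sweep", "tbl_df", "tbl", "data.frame"))
}

#' Estimate the niche-competition loss rate from paired experiments
#'
#' Under the logistic model the classical slope measures grazing plus niche
#' competition while the Z-dilution slope measures grazing alone, so their
#' difference estimates the per-capita niche-competition loss rate r P0 / K.
#' Both assessments must come from the same parameters, model and
#' incubation time.
#'
#' @param classical,zdil One-row `dilution_assessment` tibbles from
#'   [assess_method()] using the classical and Z-dilution designs.
#' @return Estimated niche-competition loss rate, day^-1.
#' @examples
#' p <- scenario_params("high")
#' cl <- assess_method(experiment_design("classical"), p)
#' zd <- assess_method(experiment_design("z-dilution"), p)
#' estimate_niche_competition(cl, zd)
#' @export
estimate_niche_competition <- function(classical, zdil) {
  stopifnot(inherits(classical, "dilution_assessment"),
            inherits(zdil, "dilution_assessment"))
  if (classical$method != "classical" || zdil$method != "z-dilution") {
    abort("Arguments must be a classical and a z-dilution assessment, in that order.")
  }
  same <- identical(attr(classical, "params"), attr(zdil, "params")) &&
    identical(attr(classical, "model"), attr(zdil, "model")) &&
    identical(attr(classical, "design")$incubation, attr(zdil, "design")$incubation)
  if (!same) {
    abort("Mismatched provenance: both assessments must share parameters, model and incubation time.")
  }
  classical$mortality_estimate - zdil$mortality_estimate
}

#' Tidiers for dilution-curve fits
#'
#' `tidy()` returns the per-term OLS coefficients of the dilution-curve
#' regression; `glance()` returns a one-row summary with the ecological
#' reading of the fit (growth and mortality estimates).
#'
#' @param x A `dilution_fit` from [fit_dilution_curve()].
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name dilution_fit_tidiers
NULL

#' @rdname dilution_fit_tidiers
#' @export
tidy.dilution_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(s), estimate = unname(s[, "Estimate"]),
         std.error = unname(s[, "Std. Error"]))
}

#' @rdname dilution_fit_tidiers
#' @export
glance.dilution_fit <- function(x, ...) {
  tibble(growth_estimate = x$growth_estimate,
         mortality_estimate = x$mortality_estimate,
         r.squared = x$r_squared, nobs = x$n)
}
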