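#' Ecosystem parameter bundle
#'
#' Bundles the four ecological parameters that govern bottle dynamics:
#' the intrinsic per-capita phytoplankton growth rate `r`, the carrying
#' capacity `K`, the microzooplankton clearance (filtering) rate `a`, and
#' the ambient microzooplankton density `Z0`. Defaults other than `Z0`
#' are the study's standard values (r = 1 per day, K = 2.2e7 cells per ml,
#' a = 4.8e-5 ml per grazer per day).
#'
#' @param r Intrinsic per-capita phytoplankton growth rate, day^-1. Must be
#'   positive.
#' @param K Phytoplankton carrying capacity, cells ml^-1. Must be positive.
#' @param a Microzooplankton clearance rate, ml grazer^-1 day^-1. Must be
#'   non-negative.
#' @param Z0 Ambient microzooplankton density, grazers ml^-1. Must be
#'   non-negative.
#'
#' @return An object of class `ecosystem_params`: a named list with fields
#'   `r`, `K`, `a`, `Z0`.
#' @seealso [scenario_params()] for the named low/intermediate/high presets,
#'   [grazing_pressure()], [steady_state_density()], [baseline_mortality()].
#' @examples
#' p <- ecosystem_params(Z0 = 20000)
#' grazing_pressure(p)  # 0.96
#' @export
ecosystem_params <- function(r = 1, K = 2.2e7, a = 4.8e-5, Z0) {
  stopifnot(is.numeric(r), length(r) == 1, is.numeric(K), length(K) == 1,
            is.numeric(a), length(a) == 1, is.numeric(Z0), length(Z0) == 1)
  if (!is.finite(r) || r <= 0) abort("`r` must be a positive finite number.")
  if (!is.finite(K) || K <= 0) abort("`K` must be a positive finite number.")
  if (!is.finite(a) || a < 0) abort("`a` must be a non-negative finite number.")
  if (!is.finite(Z0) || Z0 < 0) abort("`Z0` must be a non-negative finite number.")
  structure(list(r = r, K = K, a = a, Z0 = Z0), class = "ecosystem_params")
}

#' @export
print.ecosystem_params <- function(x, ...) {
  cat("<ecosystem_params>\n")
  cat(sprintf("  r  = %g day^-1\n  K  = %g cells/ml\n  a  = %g ml/(grazer day)\n  Z0 = %g grazers/ml\n",
              x$r, x$K, x$a, x$Z0))
  cat(sprintf("  grazing pressure delta_Z = %g\n", grazing_pressure(x)))
  invisible(x)
}

# canonical scenario presets: ambient grazer densities at the three
# highlighted levels of grazing pressure
.scenario_Z0 <- c(low = 1000, intermediate = 10000, high = 20000)

#' Named grazing-pressure scenario presets
#'
#' Returns the standard parameter bundle for one of the three highlighted
#' grazing-pressure scenarios. All three share r = 1 /day, K = 2.2e7 cells/ml
#' and a = 4.8e-5 ml/(grazer day); they differ only in ambient grazer
#' density: low (Z0 = 1000, delta_Z = 0.048), intermediate (Z0 = 10000,
#' delta_Z = 0.48) and high (Z0 = 20000, delta_Z = 0.96).
#'
#' @param scenario One of `"low"`, `"intermediate"`, `"high"`.
#' @return An [ecosystem_params()] object.
#' @examples
#' scenario_params("high")
#' @export
scenario_params <- function(scenario = c("low", "intermediate", "high")) {
  scenario <- match.arg(scenario)
  ecosystem_params(Z0 = .scenario_Z0[[scenario]])
}

#' Grazing pressure
#'
#' The fractional depression of the steady-state phytoplankton density
#' caused by grazing: delta_Z = 1 - P*_Z / P*_A = a Z0 / r. Zero means no
#' grazing; 1 means grazing draws the population to extinction.
#'
#' @param params An [ecosystem_params()] object.
#' @return Dimensionless grazing pressure a*Z0/r (not clamped).
#' @export
grazing_pressure <- function(params) {
  stopifnot(inherits(params, "ecosystem_params"))
  params$a * params$Z0 / params$r
}

#' Baseline grazing mortality rate
#'
#' The true per-capita grazing loss rate m = a * Z0 that a dilution
#' experiment aims to estimate.
#'
#' @inheritParams grazing_pressure
#' @return Mortality rate, day^-1.
#' @export
baseline_mortality <- function(params) {
  stopifnot(inherits(params, "ecosystem_params"))
  params$a * params$Z0
}

#' Steady-state phytoplankton density
#'
#' Without grazers the logistic model equilibrates at the carrying capacity,
#' P*_A = K. With grazers at ambient density Z0 the steady state is
#' P*_Z = K (1 - a Z0 / r), which is positive only while the grazing
#' pressure a Z0 / r stays below 1.
#'
#' @inheritParams grazing_pressure
#' @param with_grazers If `TRUE` (default), return P*_Z; otherwise P*_A = K.
#' @return Density, cells ml^-1.
#' @examples
#' steady_state_density(scenario_params("high"))  # 8.8e5
#' @export
steady_state_density <- function(params, with_grazers = TRUE) {
  stopifnot(inherits(params, "ecosystem_params"))
  if (!with_grazers) return(params$K)
  delta <- grazing_pressure(params)
  if (delta > 1) {
    abort(sprintf(
      "Invalid regime: grazing pressure delta_Z = %g exceeds 1, so the grazed steady state is negative.",
      delta))
  }
  params$K * (1 - delta)
}
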