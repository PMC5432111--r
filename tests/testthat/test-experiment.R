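test_that("experiment designs validate fractions, incubation and P0", {
  expect_s3_class(experiment_design(), "experiment_design")
  expect_error(experiment_design(fractions = 0.5), "at least two")
  expect_error(experiment_design(fractions = c(0, 0.5)), "\\(0, 1\\]")
  expect_error(experiment_design(fractions = c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(experiment_design(fractions = c(0.5, 0.5, 1)), "increasing")
  expect_error(experiment_design(incubation = 0), "incubation")
  expect_error(experiment_design(P0 = -1), "P0")
  expect_error(experiment_design(P0 = "ambient"), "P0")
})

test_that("bottle series dilute the right populations for each design", {
  high <- scenario_params("high")
  low <- scenario_params("low")

  cl <- dilution_series(experiment_design("classical"), high)
  expect_equal(nrow(cl), 10)
  # undiluted bottle is whole seawater: (P*, Z0)
  expect_equal(cl$P_init[10], steady_state_density(high))
  expect_equal(cl$Z[10], high$Z0)

  zd <- dilution_series(experiment_design("z-dilution"), high)
  # z-dilution keeps phytoplankton ambient, dilutes grazers only
  expect_equal(zd$P_init, rep(8.8e5, 10))
  expect_equal(zd$Z[zd$F == 0.5], 10000)

  cl_low <- dilution_series(experiment_design("classical"), low)
  expect_equal(cl_low$P_init[1], 0.1 * 0.952 * 2.2e7)  # = 2.0944e6
  expect_equal(cl_low$Z[1], 100)

  # steady-state initialisation is meaningless past the extinction threshold
  p_over <- ecosystem_params(r = 1, K = 2.2e7, a = 1e-4, Z0 = 15000)
  expect_error(dilution_series(experiment_design(), p_over), "Invalid regime")
  # ...but a numeric P0 lets the declining regime be simulated
  ok <- dilution_series(experiment_design(P0 = 1e6), p_over)
  expect_equal(ok$P_init, ok$F * 1e6)
})

test_that("apparent growth rate is the log-ratio rate and rejects bad inputs", {
  expect_identical(apparent_growth_rate(1e6, 1e6, T = 3), 0)
  r <- 0.7
  expect_equal(apparent_growth_rate(2e5, 2e5 * exp(r * 2), T = 2), r)
  expect_error(apparent_growth_rate(0, 1e5, T = 1), "positive")
  expect_error(apparent_growth_rate(1e5, -1, T = 1), "positive")
  expect_error(apparent_growth_rate(1e5, 1e5, T = 0), "T")
})

test_that("the classical theory is exact when its exponential model is true", {
  for (sc in c("low", "intermediate", "high")) {
    p <- scenario_params(sc)
    fit <- experiment_design("classical") |>
      run_dilution_experiment(p, model = "exponential") |>
      fit_dilution_curve()
    expect_lt(rel_err(fit$mortality_estimate, baseline_mortality(p)), 1e-10)
    expect_lt(rel_err(fit$growth_estimate, p$r), 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  }
})

test_that("undiluted steady-state bottles show zero apparent growth in both designs", {
  p <- scenario_params("intermediate")
  for (m in c("classical", "z-dilution")) {
    curve <- run_dilution_experiment(experiment_design(m), p, "logistic")
    expect_true(all(is.finite(curve$r_tilde)))
    expect_equal(curve$r_tilde[curve$F == 1], 0, tolerance = 1e-10)
  }
})

test_that("the dilution-curve regression recovers exact lines and frozen mortalities", {
  # OLS on an exact line is exact
  F <- seq(0.1, 1, by = 0.1)
  exact <- tibble::tibble(F = F, r_tilde = 1 - 0.048 * F)
  fit <- fit_dilution_curve(exact)
  expect_equal(fit$slope, -0.048, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$mortality_estimate, -fit$slope)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # frozen against an independent adaptive-step ODE + least-squares oracle
  fit_low <- experiment_design("classical") |>
    run_dilution_experiment(scenario_params("low"), "logistic") |>
    fit_dilution_curve()
  expect_equal(fit_low$mortality_estimate, 0.9238541413, tolerance = 1e-6)

  # high grazing pressure: classical estimate within 5% of the true 0.96/day
  fit_high <- experiment_design("classical") |>
    run_dilution_experiment(scenario_params("high"), "logistic") |>
    fit_dilution_curve()
  expect_lt(abs(fit_high$mortality_estimate - 0.96) / 0.96, 0.05)

  expect_error(fit_dilution_curve(tibble::tibble(F = c(0.5, 0.5),
                                                 r_tilde = c(1, 2))),
               "Degenerate")
})

test_that("short incubations converge to the instantaneous dilution-line slopes", {
  for (sc in c("low", "high")) {
    p <- scenario_params(sc)
    Pstar <- steady_state_density(p)
    m <- baseline_mortality(p)
    cl <- experiment_design("classical", incubation = 1e-4) |>
      run_dilution_experiment(p, "logistic") |> fit_dilution_curve()
    zd <- experiment_design("z-dilution", incubation = 1e-4) |>
      run_dilution_experiment(p, "logistic") |> fit_dilution_curve()
    # classical slope -> r P*/K + aZ0 (= r at steady state), intercept -> r
    expect_lt(rel_err(-cl$slope, p$r * Pstar / p$K + m), 0.005)
    expect_lt(rel_err(cl$intercept, p$r), 0.005)
    # z-dilution slope and intercept -> aZ0
    expect_lt(rel_err(-zd$slope, m), 0.005)
    expect_lt(rel_err(zd$intercept, m), 0.005)
  }
})

test_that("estimates are insensitive to the number of dilution levels", {
  p <- scenario_params("intermediate")
  for (m in c("classical", "z-dilution")) {
    f10 <- experiment_design(m, fractions = seq(0.1, 1, length.out = 10)) |>
      run_dilution_experiment(p) |> fit_dilution_curve()
    f20 <- experiment_design(m, fractions = seq(0.1, 1, length.out = 20)) |>
      run_dilution_experiment(p) |> fit_dilution_curve()
    expect_lt(rel_err(f20$mortality_estimate, f10$mortality_estimate), 0.02)
    expect_lt(rel_err(f20$growth_estimate, f10$growth_estimate), 0.02)
  }
})

test_that("tidy() and glance() expose the fit in broom style", {
  fit <- experiment_design() |>
    run_dilution_experiment(scenario_params("high")) |>
    fit_dilution_curve()
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("(Intercept)", "F"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mortality_estimate, fit$mortality_estimate)
  expect_equal(gl$nobs, 10)
})

test_that("autoplot methods return ggplot objects", {
  curve <- run_dilution_experiment(experiment_design(), scenario_params("low"))
  expect_s3_class(autoplot(curve), "ggplot")
  sw <- sweep_grazing_pressure(c(0.1, 0.5, 0.9))
  expect_s3_class(autoplot(sw), "ggplot")
})
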