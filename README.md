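# zdilution

Simulation framework for assessing how well **dilution experiments** — the
standard method for estimating microzooplankton grazing rates on
phytoplankton — recover the true grazing mortality rate when phytoplankton
also compete with each other for resources (niche competition).

It is aimed at plankton ecologists and modellers who use or interpret
dilution-method rate estimates and want to know when the classical design is
trustworthy, and at anyone exploring the proposed **Z-dilution** alternative,
in which only the grazers are diluted.

## The model and the two designs

Phytoplankton density *P* inside an incubation bottle follows logistic
growth with grazing by a constant grazer density *Z*:

    dP/dt = r P (1 - P/K) - a P Z

with intrinsic growth rate *r* (day⁻¹), carrying capacity *K* (cells ml⁻¹)
and clearance rate *a* (ml grazer⁻¹ day⁻¹). The quantity a dilution
experiment targets is the baseline grazing mortality *m = a Z₀*. Grazing
pressure is summarised by δ_Z = a Z₀ / r ∈ [0, 1): the fractional depression
of the steady state P\* = K (1 − δ_Z) caused by grazers.

A bottle at dilution fraction *F* starts at:

| design     | phytoplankton | grazers |
|------------|---------------|---------|
| classical  | F P₀          | F Z₀    |
| Z-dilution | P₀            | F Z₀    |

Each bottle is incubated (default 24 h) and the apparent growth rate
r̃ = (1/T) ln(P_T / P₀) is regressed on *F*; the intercept estimates growth
and the negative slope estimates mortality. Under the logistic model the
classical slope is *r P₀/K + a Z₀* — grazing **plus** niche competition —
so the classical method overestimates grazing whenever competition matters.
The Z-dilution slope is *a Z₀* alone, and the difference between the two
slopes estimates the niche-competition loss rate *r P₀/K*. With constant
*Z* the bottle dynamics have an exact effective-logistic closed form
(rate r′ = r − aZ, capacity K′ = K r′/r), so everything here is
deterministic and fast.

## Worked example

```r
library(zdilution)

p <- scenario_params("low")      # r = 1/day, K = 2.2e7, a = 4.8e-5, Z0 = 1000
grazing_pressure(p)
#> [1] 0.048
baseline_mortality(p)            # the true grazing rate, day^-1
#> [1] 0.048

experiment_design("classical") |>
  run_dilution_experiment(p, model = "logistic") |>
  fit_dilution_curve()
#> <dilution_fit>  r_tilde ~ F (ordinary least squares)
#>   growth estimate (intercept): 0.880272 day^-1
#>   mortality estimate (-slope): 0.923854 day^-1
#>   R-squared: 0.987302   (n = 10 bottles)

assess_method(experiment_design("classical"), p)$bias
#> [1] 19.24696
```

The classical design reports a mortality rate of 0.92 day⁻¹ against a true
grazing rate of 0.048 day⁻¹ — a ≈19-fold overestimate, because at this low
grazing pressure almost all realised mortality is niche competition, which
the classical slope absorbs. The same experiment with
`experiment_design("z-dilution")` gives 0.031 day⁻¹, an underestimate but a
far smaller error. `sweep_grazing_pressure()` maps both biases across the
whole δ_Z gradient and `autoplot()` draws the standard figures.

A command-line interface (`curve`, `compare`, `sweep`, `fixtures`
subcommands) is installed at
`system.file("cli", "zdilution", package = "zdilution")`; see
`?run_cli` and `vignettes/dilution-method-bias.Rmd` for details.

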