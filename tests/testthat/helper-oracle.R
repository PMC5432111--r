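# Independent numerical oracle: adaptive-step integration of the bottle ODE
# with deSolve, used to cross-check the closed-form solution.
ode_bottle <- function(P_init, Z, params, model = "logistic", t = 1,
                       rtol = 1e-10, atol = 1e-6) {
  rhs <- function(time, state, parms) {
    P <- state[[1]]
    growth <- if (model == "logistic") {
      params$r * P * (1 - P / params$K)
    } else {
      params$r * P
    }
    list(growth - params$a * P * Z)
  }
  sol <- deSolve::ode(c(P = P_init), times = c(0, t), func = rhs, parms = NULL,
                      rtol = rtol, atol = atol)
  unname(sol[nrow(sol), "P"])
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
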