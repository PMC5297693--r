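# Independent oracles and fixture builders used across the test files.

# Central finite-difference Jacobian of the public rhs.
fd_jacobian <- function(state, params, h = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- numeric(4)
    e[j] <- h
    J[, j] <- (upr_rhs(state + e, params) - upr_rhs(state - e, params)) / (2 * h)
  }
  J
}

# Fully uncoupled network with linear (mass-action) inducer fluxes: no
# sensor cross-activation, no double-negative loop, infinite Michaelis
# constants.  Each node then has the closed-form steady state
# X* = T * a / (a + d).
uncoupled_linear_params <- function(stress = 10) {
  default_params(stress = stress,
                 k_ip = 0, k_pi = 0, k_x_aa = 0, k_x_apa = 0,
                 J_a_on = Inf, J_a_off = Inf, J_ap_on = Inf, J_ap_off = Inf,
                 check = FALSE)
}

# Closed-form steady state of the uncoupled linear network.
closed_form_steady <- function(params) {
  p <- unclass(params)
  S <- p[["stress"]]
  perk <- p[["PERKT"]] * p[["k_sp"]] * S / (p[["k_sp"]] * S + p[["k_dp"]])
  ire1 <- p[["IRE1T"]] * p[["k_si"]] * S / (p[["k_si"]] * S + p[["k_di"]])
  aA <- p[["k_pa"]] * perk + p[["k_ia"]] * ire1
  aD <- p[["k_pap"]] * perk + p[["k_iap"]] * ire1
  auto <- p[["AT_auto"]] * aA / (aA + p[["k_da"]])
  apop <- p[["AT_apop"]] * aD / (aD + p[["k_dap"]])
  c(perk = perk, ire1 = ire1, auto = auto, apop = apop)
}

# Brute-force steady-state oracle: integrate to convergence from a grid of
# initial states and cluster the endpoints (finds the stable states).
multistart_integration_oracle <- function(params, n_per_axis = 6, t_end = 4000,
                                          cluster_tol = 1e-4) {
  totals <- state_totals(params)
  levels <- seq(0.01, 0.99, length.out = n_per_axis)
  grid <- as.matrix(expand.grid(perk = levels * totals[["perk"]],
                                ire1 = levels * totals[["ire1"]],
                                auto = levels * totals[["auto"]],
                                apop = levels * totals[["apop"]]))
  ends <- t(apply(grid, 1, function(x0) {
    sol <- deSolve::lsoda(x0, times = seq(0, t_end, length.out = 9),
                          func = uprswitch:::.upr_deriv,
                          parms = as.numeric(unclass(params)[uprswitch:::.upr_param_names]),
                          jacfunc = uprswitch:::.upr_jac, jactype = "fullusr",
                          rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
    sol[nrow(sol), c("perk", "ire1", "auto", "apop")]
  }))
  # greedy clustering of endpoints
  centers <- list()
  for (i in seq_len(nrow(ends))) {
    x <- ends[i, ]
    hit <- FALSE
    for (k in seq_along(centers)) {
      if (max(abs(centers[[k]] - x)) < cluster_tol) { hit <- TRUE; break }
    }
    if (!hit) centers[[length(centers) + 1L]] <- x
  }
  do.call(rbind, centers)
}

# Evaluate the derivative lines of an exported .ode text at a state, using
# plain R arithmetic on the parsed expressions (text-evaluation oracle).
eval_ode_text <- function(lines, state, params) {
  eqs <- grep("^d[a-z0-9]+/dt=", lines, value = TRUE)
  env <- as.list(c(unclass(params), state))
  vapply(c("perk", "ire1", "auto", "apop"), function(v) {
    rhs_txt <- sub(sprintf("^d%s/dt=", v), "", eqs[grep(sprintf("^d%s/dt=", v), eqs)])
    eval(parse(text = rhs_txt), envir = env)
  }, numeric(1))
}

random_interior_states <- function(n, params, seed) {
  totals <- state_totals(params)
  set.seed(seed)
  mat <- matrix(runif(4 * n, min = 0.02, max = 0.98), ncol = 4)
  sweep(mat, 2, totals, `*`)
}
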