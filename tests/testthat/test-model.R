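test_that("the origin is a fixed point at zero stress", {
  d <- upr_rhs(c(perk = 0, ire1 = 0, auto = 0, apop = 0), default_params(stress = 0))
  expect_identical(unname(d), c(0, 0, 0, 0))
})

test_that("rates on the box faces never point outside the box", {
  p <- default_params(stress = 40)
  totals <- state_totals(p)
  set.seed(11)
  for (i in 1:25) {
    x <- runif(4) * totals
    face <- sample(1:4, 1)
    # lower face: derivative must be >= 0; upper face: <= 0
    x_lo <- x; x_lo[face] <- 0
    expect_gte(upr_rhs(x_lo, p)[face], 0)
    x_hi <- x; x_hi[face] <- totals[face]
    expect_lte(upr_rhs(x_hi, p)[face], 0)
  }
})

test_that("non-finite input is rejected", {
  p <- default_params()
  expect_error(upr_rhs(c(NA, 0, 0, 0), p), "non-finite")
  expect_error(upr_rhs(c(Inf, 0, 0, 0), p), "non-finite")
})

test_that("analytic Jacobian matches central finite differences", {
  p <- default_params(stress = 30)
  states <- random_interior_states(20, p, seed = 202)
  for (i in seq_len(nrow(states))) {
    x <- states[i, ]
    Ja <- upr_jacobian(x, p)
    Jn <- fd_jacobian(x, p)
    rel <- max(abs(Ja - Jn)) / max(abs(Jn))
    expect_lt(rel, 1e-5)
  }
  # also in the linear-flux limit (infinite Michaelis constants)
  pl <- uncoupled_linear_params(stress = 12)
  x <- c(perk = 0.4, ire1 = 0.3, auto = 0.6, apop = 0.2)
  expect_lt(max(abs(upr_jacobian(x, pl) - fd_jacobian(x, pl))), 1e-6)
})

test_that("uncoupled linear network recovers the closed-form steady state", {
  p <- uncoupled_linear_params(stress = 10)
  ss <- find_steady_states(p)
  expect_equal(nrow(ss), 1L)
  expect_true(ss$stable)
  expect_lt(max(abs(unlist(ss[1, c("perk", "ire1", "auto", "apop")]) -
                    closed_form_steady(p))), 1e-8)
})

test_that("uncoupled steady states are non-decreasing in stress", {
  # with the double-negative couplings removed the input layer is monotone
  p0 <- default_params(k_x_aa = 0, k_x_apa = 0, k_ip = 0, k_pi = 0, check = FALSE)
  grid <- seq(0, 60, by = 5)
  states <- t(vapply(grid, function(s) {
    ps <- p0
    ps[["stress"]] <- s
    ss <- find_steady_states(ps)
    expect_equal(nrow(ss), 1L)
    unlist(ss[1, c("perk", "ire1", "auto", "apop")])
  }, numeric(4)))
  for (j in 1:4) expect_true(all(diff(states[, j]) >= -1e-9))
})
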