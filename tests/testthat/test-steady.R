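test_that("located steady states have vanishing right-hand sides", {
  for (s in c(0, 16, 25, 40)) {
    p <- default_params(stress = s)
    ss <- find_steady_states(p)
    for (i in seq_len(nrow(ss))) {
      x <- unlist(ss[i, c("perk", "ire1", "auto", "apop")])
      expect_lt(max(abs(upr_rhs(x, p))), 1e-9)
      expect_true(all(x >= 0 & x <= state_totals(p) + 1e-12))
    }
  }
})

test_that("zero-stress equilibria reflect the self-sustaining sensor feedback", {
  # the intact network is an irreversible switch: at stress 0 the sensors
  # self-sustain (cross-activation gain > 1), so besides the origin (an
  # unstable equilibrium) both the survival and the committed death state
  # persist -- the structural basis of the wash-out argument
  ss <- find_steady_states(default_params(stress = 0))
  expect_equal(sum(ss$stable), 2L)
  origin <- ss[apply(ss[, c("perk", "ire1", "auto", "apop")], 1, max) < 1e-9, ]
  expect_equal(nrow(origin), 1L)
  expect_false(origin$stable)
  death <- ss[ss$stable & ss$apop > 0.5, ]
  surv <- ss[ss$stable & ss$apop < 0.5, ]
  expect_equal(nrow(death), 1L)
  expect_equal(nrow(surv), 1L)
  expect_gt(surv$auto, 0.9)

  # under either knockdown the feedback gain drops below one: the sensors
  # die out at stress 0 and the origin is the unique (stable) state
  for (pre in c("siPERK", "IRE1low")) {
    pk <- preset_params(pre, default_params(stress = 0))
    ssk <- find_steady_states(pk)
    expect_equal(nrow(ssk), 1L)
    expect_true(ssk$stable)
    expect_lt(max(abs(unlist(ssk[1, c("perk", "ire1", "auto", "apop")]))), 1e-9)
  }
})

test_that("root finding agrees with the multi-start integration oracle", {
  # inside the bistable window: the two stable states found by Newton must
  # match the endpoint clusters of brute-force integration
  p <- default_params(stress = 16)
  ss <- find_steady_states(p)
  stable <- as.matrix(ss[ss$stable, c("perk", "ire1", "auto", "apop")])
  oracle <- multistart_integration_oracle(p, n_per_axis = 4)
  expect_equal(nrow(oracle), nrow(stable))
  for (i in seq_len(nrow(stable))) {
    d <- apply(oracle, 1, function(o) max(abs(o - stable[i, ])))
    expect_lt(min(d), 1e-6)
  }
})

test_that("an empty start set is rejected", {
  expect_error(find_steady_states(default_params(), grid = FALSE), "no start states")
})
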