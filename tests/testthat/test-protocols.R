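test_that("protocol validation catches malformed schedules", {
  expect_error(upr_protocol(data.frame(time = c(5, 10), stress = c(1, 2)),
                            horizon = 20), "start at time 0")
  expect_error(upr_protocol(data.frame(time = c(0, 0), stress = c(1, 2)),
                            horizon = 20), "strictly increasing")
  expect_error(upr_protocol(-1, horizon = 20), "stress must be >= 0")
  expect_error(upr_protocol(10, horizon = 0), "horizon")
  expect_error(upr_protocol(10, horizon = 10, dt = 0), "dt")
})

test_that("zero stress from the origin stays at the origin", {
  tr <- integrate_protocol(default_params(), upr_protocol(0, horizon = 100))
  expect_lt(max(abs(as.matrix(tr[, c("perk", "ire1", "auto", "apop")]))), 1e-9)
  expect_true(attr(tr, "settled"))
})

test_that("step-stress trajectories settle onto the curve's stable branches", {
  p <- default_params()
  ss40 <- find_steady_states(default_params(stress = 40))
  high <- max(ss40$apop[ss40$stable])
  tr40 <- run_scenario("high_stress", p, horizon = 400)
  expect_lt(abs(tr40$apop[nrow(tr40)] - high), 1e-3)

  ss25 <- find_steady_states(default_params(stress = 25))
  low <- min(ss25$apop[ss25$stable])
  tr25 <- run_scenario("low_stress", p, horizon = 400)
  expect_lt(abs(tr25$apop[nrow(tr25)] - low), 1e-3)
})

test_that("trajectories started inside the box stay inside the box", {
  p <- default_params(stress = 40)
  totals <- state_totals(p)
  starts <- random_interior_states(6, p, seed = 7)
  for (i in seq_len(nrow(starts))) {
    tr <- integrate_protocol(p, upr_protocol(40, horizon = 500,
                                             initial_state = starts[i, ]))
    m <- as.matrix(tr[, c("perk", "ire1", "auto", "apop")])
    expect_true(all(m >= -1e-8))
    expect_true(all(sweep(m, 2, totals, `-`) <= 1e-8))
  }
})

test_that("scenario kinetics reproduce the reported phenotypes", {
  p <- default_params()
  tot <- state_totals(p)

  # high stress: autophagy rises first, then falls as apoptosis switches on
  tr40 <- run_scenario("high_stress", p)
  t_auto_peak <- tr40$time[which.max(tr40$auto)]
  cross <- tr40$time[which(tr40$apop >= 0.5 * tot[["apop"]])[1]]
  expect_lt(t_auto_peak, cross)
  expect_gt(max(tr40$auto), 0.8)                    # a real autophagy window
  expect_lt(tr40$auto[nrow(tr40)], 0.1)             # shut off by apoptosis
  expect_gt(tr40$apop[nrow(tr40)], 0.9)

  # siPERK at high stress: death never switches on, autophagy persists
  trs <- run_scenario("siPERK_high_stress", p)
  expect_lt(max(trs$apop), 0.5 * tot[["apop"]])
  expect_gt(trs$auto[nrow(trs)], 0.9)

  # IRE1-low at high stress: earlier death than the intact network
  tri <- run_scenario("IRE1low_high_stress", p)
  onset_i <- tri$time[which(tri$apop >= 0.5 * tot[["apop"]])[1]]
  expect_lt(onset_i, cross)

  # mutual exclusion along every scenario trajectory's settled tail
  for (tr in list(tr40, trs, tri)) {
    tail_rows <- tr[tr$time > max(tr$time) * 0.9, ]
    expect_false(any(tail_rows$auto > 0.5 & tail_rows$apop > 0.5))
  }
})

test_that("wash-out after commitment does not release the death state", {
  tr <- run_scenario("washout", default_params())
  ev <- attr(tr, "events")
  expect_equal(nrow(ev), 2L)
  expect_identical(ev$stress, c(40, 0))
  expect_gt(attr(tr, "wash_time"), attr(tr, "commit_time"))
  expect_gt(tr$apop[nrow(tr)], 0.9)   # still committed at zero stress
  expect_lt(tr$auto[nrow(tr)], 0.1)
})

test_that("unknown scenarios are rejected", {
  expect_error(run_scenario("explodes"), "unknown scenario")
})
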