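# Coarse scans (n = 120-150) are used here for speed; the full-resolution
# production scan is exercised by the acceptance tests.

curve_cache <- new.env()
default_curve <- function() {
  if (is.null(curve_cache$def)) {
    curve_cache$def <- signal_response(default_params(), n = 150)
  }
  curve_cache$def
}

test_that("the intact network yields a bistable, irreversible response", {
  cv <- default_curve()
  expect_s3_class(cv, "upr_curve")
  expect_equal(max_stable_states(cv), 2L)
  expect_identical(cv$sn_on_status, "found")
  expect_gt(cv$sn_on, 25)
  expect_lt(cv$sn_on, 40)
  expect_identical(cv$sn_off_status, "below_scan_min")
  expect_identical(classify_reversibility(cv), "irreversible")

  # inside the window: a low branch, a high branch, a separating unstable one
  pts <- cv$points
  inside <- pts[pts$stress > 10 & pts$stress < 25, ]
  per_stress <- split(inside, inside$stress)
  for (ps in per_stress) {
    expect_equal(sum(ps$stable), 2L)
    expect_gte(sum(!ps$stable), 1L)
    expect_true(min(ps$apop[ps$stable]) < min(ps$apop[!ps$stable]))
    expect_true(max(ps$apop[ps$stable]) > max(ps$apop[!ps$stable]))
  }
})

test_that("removing the double-negative loop leaves a monostable response", {
  p <- default_params(k_x_aa = 0, k_x_apa = 0, check = FALSE)
  cv <- signal_response(p, n = 120)
  expect_equal(max_stable_states(cv), 1L)
  expect_identical(cv$sn_on_status, "no_fold")
  expect_identical(classify_reversibility(cv), "no_switch")
})

test_that("knockdown presets reverse the switch and shift its threshold", {
  sip <- signal_response(preset_params("siPERK"), n = 120)
  expect_identical(classify_reversibility(sip), "reversible")
  expect_identical(sip$sn_on_status, "above_scan_max")
  expect_gt(sip$sn_off, 0)

  ire <- signal_response(preset_params("IRE1low"), n = 120)
  expect_identical(classify_reversibility(ire), "reversible")
  expect_identical(ire$sn_on_status, "found")
  expect_lt(ire$sn_on, default_curve()$sn_on)
  expect_gt(ire$sn_off, 0)
})

test_that("threshold shifts have the reported directions", {
  p <- default_params()
  expect_equal(threshold_shift(p, p, n = 120), 0)
  # siPERK's activation fold leaves the scanned range: +Inf shift
  expect_identical(threshold_shift(p, preset_params("siPERK"), n = 120), Inf)
  expect_lt(threshold_shift(p, preset_params("IRE1low"), n = 120), 0)
})

test_that("perturbations relax back to stable branch points and leave the saddle", {
  p16 <- default_params(stress = 16)
  ss <- find_steady_states(p16)
  stable_states <- ss[ss$stable, c("perk", "ire1", "auto", "apop")]
  saddle <- unlist(ss[!ss$stable & ss$apop > 1e-3, c("perk", "ire1", "auto", "apop")][1, ])

  relax <- function(x0) {
    tr <- integrate_protocol(p16, upr_protocol(16, horizon = 3000,
                                               initial_state = x0))
    unlist(tr[nrow(tr), c("perk", "ire1", "auto", "apop")])
  }
  set.seed(31)
  for (i in seq_len(nrow(stable_states))) {
    x0 <- unlist(stable_states[i, ]) + runif(4, -1e-3, 1e-3)
    expect_lt(max(abs(relax(x0) - unlist(stable_states[i, ]))), 1e-4)
  }
  # off the saddle: must end on one of the two stable states, not the saddle
  for (sgn in c(-1, 1)) {
    endp <- relax(saddle + sgn * c(0, 0, 1e-3, -1e-3))
    d_saddle <- max(abs(endp - saddle))
    d_stable <- min(apply(stable_states, 1, function(s) max(abs(endp - s))))
    expect_gt(d_saddle, 0.05)
    expect_lt(d_stable, 1e-4)
  }
})
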