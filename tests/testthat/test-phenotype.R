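test_that("degenerate series give empty features", {
  f <- extract_features(rep(0, 20), scale = 0)
  expect_equal(f$window, 0)
  expect_true(is.na(f$onset_time))
  expect_false(f$transient)

  short <- extract_features(c(0, 1), scale = 1, sustain = 3)
  expect_true(short$undetermined)
})

test_that("a square pulse is measured to within one sampling step", {
  time <- 0:100
  for (w in c(10, 25, 60)) {
    values <- as.numeric(time >= 20 & time < 20 + w)
    f <- extract_features(values, time, scale = 1)
    expect_lte(abs(f$window - w), 1)
    # the pulse recedes for good: a transient, not an onset
    expect_true(is.na(f$onset_time))
    expect_true(f$transient)
  }
  # a terminal step is a sustained onset
  values <- as.numeric(time >= 40)
  f <- extract_features(values, time, scale = 1)
  expect_equal(f$onset_time, 40)
  expect_false(f$transient)
})

test_that("sustained onsets tolerate noise dips shorter than the guard", {
  time <- 0:60
  values <- as.numeric(time >= 30)
  values[c(41, 52)] <- 0   # isolated dips shorter than `sustain`
  f <- extract_features(values, time, scale = 1)
  expect_equal(f$onset_time, 30)
  # but a sustained deactivation resets the onset to the terminal phase
  values2 <- as.numeric(time >= 10)
  values2[30:40] <- 0
  f2 <- extract_features(values2, time, scale = 1)
  expect_equal(f2$onset_time, 40)
})

test_that("scenario trajectories map onto the reported phenotype vocabulary", {
  p <- default_params()
  ref <- trajectory_features(run_scenario("high_stress", p))

  # low stress: transient apoptosis peak, no sustained onset -> survival
  f25 <- trajectory_features(run_scenario("low_stress", p))
  expect_true(f25$apop$transient)
  expect_true(is.na(f25$apop$onset_time))
  expect_identical(call_phenotype(f25, ref)$class, "survival")

  # self-reference: plain death, never "delayed"
  expect_identical(call_phenotype(ref, ref)$class, "death")

  # siPERK: survival or delayed death, never plain death within the horizon
  fsi <- trajectory_features(run_scenario("siPERK_high_stress", p))
  expect_true(call_phenotype(fsi, ref)$class %in% c("survival", "delayed_death"))

  # IRE1-low: death with earlier onset than the intact network
  fir <- trajectory_features(run_scenario("IRE1low_high_stress", p))
  call_ir <- call_phenotype(fir, ref)
  expect_identical(call_ir$class, "death")
  expect_lt(call_ir$apoptosis_onset, ref$apop$onset_time)
})

test_that("phenotype calls are stable for onset thresholds in [0.4, 0.6]", {
  p <- default_params()
  scenarios <- c(low_stress = "survival", high_stress = "death",
                 siPERK_high_stress = "survival")
  trajs <- lapply(names(scenarios), run_scenario, params = p)
  names(trajs) <- names(scenarios)
  for (frac in c(0.4, 0.5, 0.6)) {
    ref <- trajectory_features(trajs$high_stress, onset_frac = frac)
    for (sc in names(scenarios)) {
      cl <- call_phenotype(trajectory_features(trajs[[sc]], onset_frac = frac), ref)$class
      expect_identical(cl, unname(scenarios[sc]),
                       label = sprintf("%s at onset_frac %.1f: %s", sc, frac, cl))
    }
  }
})

test_that("marker map covers every model variable", {
  mm <- marker_map()
  expect_setequal(unique(unname(mm)), c("perk", "ire1", "auto", "apop"))
  expect_true(all(c("LC3II", "ULK555P", "cPARP", "CHOP", "JNKP", "eiF2aP", "XBP1s")
                  %in% names(mm)))
})
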