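test_that("noiseless time courses equal the normalized trajectory exactly", {
  tc <- generate_timecourse(scenario = "high_stress", cv = 0, seed = 1,
                            n_replicates = 2)
  clean <- attr(tc, "noiseless")
  for (r in 1:2) {
    for (m in colnames(clean)) {
      got <- tc$intensity[tc$replicate == r & tc$marker == m]
      expect_identical(got, unname(clean[, m]))
    }
  }
  # normalization: every marker peaks at exactly 1
  expect_true(all(abs(apply(clean, 2, max) - 1) < 1e-12))
  expect_true(all(tc$intensity >= 0))
})

test_that("generation is deterministic in the seed and replicates differ", {
  a <- generate_timecourse(cv = 0.2, seed = 5)
  b <- generate_timecourse(cv = 0.2, seed = 5)
  expect_identical(a$intensity, b$intensity)
  c_ <- generate_timecourse(cv = 0.2, seed = 6)
  expect_false(identical(a$intensity, c_$intensity))
  expect_false(identical(a$intensity[a$replicate == 1],
                         a$intensity[a$replicate == 2]))
  # the caller's RNG stream is not consumed
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(generate_timecourse(cv = 0.3, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("the noise generator realises the requested coefficient of variation", {
  tc <- generate_timecourse(scenario = "high_stress", cv = 0.2, seed = 3,
                            n_replicates = 500, sampling_interval = 30)
  # per-sample empirical cv across replicates, pooled over markers/times
  key <- paste(tc$marker, tc$time)
  cvs <- vapply(split(tc$intensity, key), function(v) {
    if (mean(v) < 1e-6) return(NA_real_)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cvs <- cvs[!is.na(cvs)]
  expect_lt(abs(mean(cvs) - 0.2) / 0.2, 0.1)
})

test_that("invalid sampling or noise settings are rejected", {
  expect_error(generate_timecourse(sampling_interval = 500, horizon = 120),
               "larger than the horizon")
  expect_error(generate_timecourse(cv = -0.1), "cv")
  expect_error(generate_timecourse(n_replicates = 0), "n_replicates")
})

test_that("phenotype recovery is perfect without noise and degrades gracefully", {
  rs <- recovery_study(n_replicates = 30, cv_grid = c(0, 0.3), seed = 2)
  at0 <- rs[rs$cv == 0, ]
  expect_true(all(at0$recovery == 1))
  # the noiseless calls carry the expected biology
  expect_identical(at0$noiseless_class[at0$scenario == "low_stress"], "survival")
  expect_identical(at0$noiseless_class[at0$scenario == "high_stress"], "death")
  expect_identical(at0$noiseless_class[at0$scenario == "siPERK_high_stress"], "survival")
  expect_identical(at0$noiseless_class[at0$scenario == "IRE1low_high_stress"], "death")
  expect_true(all(rs$recovery >= 0 & rs$recovery <= 1))
})
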