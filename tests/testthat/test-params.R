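test_that("constructor enforces the wiring invariants", {
  p <- default_params()
  expect_s3_class(p, "upr_params")
  expect_true(all(unclass(p) >= 0))
  expect_gt(p[["k_ia"]], p[["k_pa"]])
  expect_gt(p[["k_pap"]], p[["k_iap"]])

  expect_error(default_params(k_ia = 0.01), "k_ia > k_pa")
  expect_error(default_params(k_ip = 0), "positive feedback")
  expect_error(default_params(k_x_aa = 0), "double-negative")
  expect_error(default_params(k_dp = -1), ">= 0")
  expect_error(default_params(nonsense = 1), "unknown")
  expect_error(upr_params(stress = 1), "missing parameters")
  # degenerate sets are allowed when checking is off
  expect_silent(default_params(k_ip = 0, k_pi = 0, check = FALSE))
})

test_that("knockdowns scale exactly one total and keep everything else", {
  p <- default_params()
  kd <- knockdown_params(p, "PERK", 0.2)
  expect_equal(kd[["PERKT"]], 0.2)
  expect_equal(unclass(kd)[setdiff(names(unclass(kd)), "PERKT")],
               unclass(p)[setdiff(names(unclass(p)), "PERKT")])

  kd2 <- knockdown_params(p, "IRE1", 0.1)
  expect_equal(kd2[["IRE1T"]], 0.1)

  # identity case
  expect_equal(unclass(knockdown_params(p, "PERK", 1.0)), unclass(p))

  expect_error(knockdown_params(p, "PERK", 0), "\\(0, 1\\]")
  expect_error(knockdown_params(p, "PERK", 1.5), "\\(0, 1\\]")
})

test_that("presets reproduce the reported knockdown levels", {
  expect_equal(preset_params("siPERK")[["PERKT"]], 0.2)
  expect_equal(preset_params("IRE1low")[["IRE1T"]], 0.1)
  expect_equal(unclass(preset_params("default")), unclass(default_params()))
})
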