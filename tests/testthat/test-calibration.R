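# The constraint suite at coarse scan resolution; full production
# resolution is exercised in the acceptance tests.

test_that("the shipped default set satisfies the behaviour catalogue", {
  rep <- check_constraints(default_params(), n_scan = 120)
  expect_s3_class(rep, "upr_constraints")
  expect_true(isTRUE(attr(rep, "overall")))
  expect_true(all(rep$pass))
  # overall is the conjunction of the individual flags
  expect_identical(isTRUE(attr(rep, "overall")), all(rep$pass))
})

test_that("destroying the toggle loop is detected as loss of bistability", {
  # severing one leg of the double-negative loop removes the switch
  p <- default_params(k_x_apa = 0, check = FALSE)
  rep <- check_constraints(p, n_scan = 60, fold_tol = 0.1)
  expect_false(rep$pass[rep$id == "C1"])
  expect_false(isTRUE(attr(rep, "overall")))

  # fully uncoupled inducers as well
  p0 <- default_params(k_x_aa = 0, k_x_apa = 0, check = FALSE)
  rep0 <- check_constraints(p0, n_scan = 60, fold_tol = 0.1)
  expect_false(rep0$pass[rep0$id == "C1"])
})

test_that("random search screens, scores and recovers feasible sets", {
  expect_length(search_parameters(n_samples = 0, seed = 1)$feasible, 0L)

  # smoke-scale search in a tight box around the shipped defaults
  sr <- search_parameters(bounds = default_search_bounds(spread = 1.05),
                          n_samples = 12, seed = 7, n_scan = 60, fold_tol = 0.1)
  expect_gte(length(sr$feasible), 1L)
  # feasibility is idempotent: re-checking a feasible set passes again
  re <- check_constraints(sr$feasible[[1L]], n_scan = 60, fold_tol = 0.1)
  expect_true(isTRUE(attr(re, "overall")))
})

test_that("robustness scan reports per-constraint outcomes", {
  rt <- robustness_table(default_params(), delta = 0.1, which = "k_sp",
                         n_scan = 60, fold_tol = 0.1)
  expect_equal(nrow(rt), 2L)
  expect_true(all(c("parameter", "direction", paste0("C", 1:8), "overall")
                  %in% names(rt)))
  expect_true(is.logical(rt$C1))
})
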