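fake_fit <- function(spec, ll) {
  structure(list(spec = spec, log_likelihood = ll,
                 n_parameters = n_parameters(spec),
                 aic = 2 * n_parameters(spec) - 2 * ll,
                 converged = TRUE),
            class = "fit_result")
}

test_that("likelihood-ratio test matches a chi-squared tail oracle", {
  full <- model_spec("symmetric_sdt")
  red <- model_spec("symmetric_sdt", bias_structure = "sensory_only")
  # no improvement: statistic 0, p = 1, reduction survives
  s0 <- likelihood_ratio_test(fake_fit(full, -100), fake_fit(red, -100))
  expect_equal(s0$lr_statistic, 0)
  expect_equal(s0$p_value, 1)
  expect_identical(s0$kept, "reduced")

  # the canonical df = 1 critical value, against numeric integration
  s1 <- likelihood_ratio_test(fake_fit(full, -100 + 3.8415 / 2),
                              fake_fit(red, -100))
  expect_equal(s1$p_value, oracle_chisq_tail(3.8415, 1), tolerance = 1e-4)
  expect_equal(round(s1$p_value, 4), 0.05)

  # df = 2 with a tiny statistic: p close to 1
  full2 <- model_spec("symmetric_sdt", lapse_structure = "two")
  red2 <- model_spec("symmetric_sdt", lapse_structure = "none",
                     fixed_lapse = 0.01)
  s2 <- likelihood_ratio_test(fake_fit(full2, -100 + 0.05),
                              fake_fit(red2, -100))
  expect_equal(s2$df, 2)
  expect_equal(s2$p_value, oracle_chisq_tail(0.1, 2), tolerance = 1e-4)
  expect_gt(s2$p_value, 0.9)
  expect_identical(s2$kept, "reduced")
})

test_that("likelihood-ratio test rejects invalid comparisons", {
  sens <- model_spec("symmetric_sdt", bias_structure = "sensory_only")
  decs <- model_spec("symmetric_sdt", bias_structure = "decisional_only")
  expect_error(
    likelihood_ratio_test(fake_fit(sens, -10), fake_fit(decs, -11)),
    "not nested")
  full <- model_spec("symmetric_sdt")
  expect_error(
    likelihood_ratio_test(fake_fit(full, -12), fake_fit(sens, -10)),
    "negative")
})

test_that("the ladder keeps the structure the data were generated with", {
  # lapses exactly at the pinned value: everything reduces to the basic model
  d0 <- simulate_group(
    design_spec(n_per_level = 60),
    params = symmetric_params(0.6, -0.2, 0.5, lam1 = 0.01, lam2 = 0.01,
                              lam1p = 0.01, lam2p = 0.01),
    seed = 101)
  sel0 <- select_structure(d0, seed = 1)
  expect_identical(sel0$spec$lapse_structure, "none")
  expect_identical(sel0$spec$n_sigmas, 1L)
  expect_identical(sel0$spec$bias_structure, "full")

  # clearly different slopes across mappings: the two-slope feature survives
  d2 <- simulate_group(
    design_spec(n_per_level = 60),
    params = symmetric_params(0.4, 0.2, sigma_primary = 0.4,
                              sigma_mirrored = 0.9, lam1 = 0.01, lam2 = 0.01,
                              lam1p = 0.01, lam2p = 0.01),
    seed = 102)
  sel2 <- select_structure(d2, seed = 1)
  expect_identical(sel2$spec$n_sigmas, 2L)

  # one strong shared lapse rate: the one-lapse structure survives
  d1 <- simulate_group(
    design_spec(n_per_level = 60),
    params = symmetric_params(0.4, 0.2, 0.5, lam1 = 0.1, lam2 = 0.1,
                              lam1p = 0.1, lam2p = 0.1),
    seed = 103)
  sel1 <- select_structure(d1, seed = 1)
  expect_identical(sel1$spec$lapse_structure, "one")
})

test_that("classification labels follow the generating bias structure", {
  d_sens <- simulate_group(experiment1_design(),
                           params = symmetric_params(1.0, 0, 0.5), seed = 111)
  cb_sens <- classify_bias(d_sens, seed = 4)
  expect_identical(cb_sens$label, "sensory")

  d_dec <- simulate_group(experiment1_design(),
                          params = symmetric_params(0, 0.5, 0.5), seed = 112)
  cb_dec <- classify_bias(d_dec, seed = 4)
  expect_identical(cb_dec$label, "decisional")

  d_both <- simulate_group(experiment1_design(),
                           params = symmetric_params(1.0, 0.5, 0.5),
                           seed = 113)
  cb_both <- classify_bias(d_both, seed = 4)
  expect_identical(cb_both$label, "sensory_plus_decisional")

  # the trail records every reduction with consistent bookkeeping
  tt <- trail_table(cb_sens$trail)
  expect_true(all(tt$p_value >= 0 & tt$p_value <= 1))
  expect_true(all(tt$lr_statistic >= 0))
  expect_true("drop_decisional" %in% tt$step)
})

test_that("classification is deterministic and order-invariant", {
  d <- simulate_group(experiment1_design(),
                      params = symmetric_params(0.6, 0.2, 0.6), seed = 121)
  cb1 <- classify_bias(d, seed = 9)
  cb2 <- classify_bias(d, seed = 9)
  expect_identical(cb1$label, cb2$label)
  expect_identical(cb1$delta_s_hat, cb2$delta_s_hat)
  # shuffling trial rows must not change the outcome
  perm <- rev(seq_len(nrow(d)))
  cb3 <- classify_bias(d[perm, ], seed = 9)
  expect_identical(cb1$label, cb3$label)
  expect_equal(cb1$delta_s_hat, cb3$delta_s_hat)
  expect_equal(trail_table(cb1$trail), trail_table(cb3$trail))
})

test_that("the key-preference diagnostic detects a true asymmetric lapse", {
  gen <- symmetric_params(0.3, 0, 0.5, lam1 = 0.02, lam2 = 0.02,
                          lam1p = 0.02, lam2p = 0.02, lam_star = 0.15)
  d <- simulate_group(design_spec(n_per_level = 60), params = gen, seed = 131)
  step <- lambda_star_check(d, seed = 6)
  expect_lt(step$p_value, 0.01)
  expect_identical(step$df, 1L)
})

test_that("indecision-generated data defeat the detection-theory account", {
  gen <- indecision_params(delta_s = 0.2, tau1 = -1, tau2 = 1, xi = 0.8,
                           sigma = 0.5)
  d <- simulate_group(design_spec(n_per_level = 100), params = gen,
                      seed = 141)
  cmp <- compare_indecision(d, seed = 7)
  expect_true(cmp$winner %in% c("indecision_full", "indecision_symmetric"))
  aic <- cmp$aic
  expect_lt(min(aic$aic[aic$model != "sdt"]),
            aic$aic[aic$model == "sdt"])
})
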