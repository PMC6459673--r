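test_that("log-likelihood reduces to log p for a single Bernoulli trial", {
  tr <- tibble::tibble(participant = "a", task = "symmetric",
                       orientation_band = "horizontal",
                       reference = "primary", orientation_deg = 0.5,
                       response = 1)
  spec <- model_spec("symmetric_sdt")
  params <- symmetric_params(delta_s = 0.2, delta_d = 0.1,
                             sigma_primary = 0.7)
  expect_equal(log_likelihood(tr, spec, params),
               log(p_choice_symmetric(0.5, params, "primary")))
})

test_that("log-likelihood matches a brute-force factorial oracle", {
  tr <- toy_trials()
  spec <- model_spec("symmetric_sdt")
  params <- symmetric_params(delta_s = 0.3, delta_d = -0.1,
                             sigma_primary = 0.8)
  cells <- choicebias:::aggregate_trials(tr)
  oracle <- sum(vapply(seq_along(cells$k), function(i) {
    p <- p_choice_symmetric(cells$theta[i], params, cells$side[i])
    oracle_log_binom(cells$k[i], cells$n[i], p)
  }, 0))
  expect_equal(log_likelihood(tr, spec, params), oracle, tolerance = 1e-10)
})

test_that("single-mapping data cannot separate the two biases", {
  # with primary-reference trials only, the likelihood depends on the biases
  # solely through their difference: shifting both together changes nothing
  d <- simulate_group(experiment1_design(),
                      params = symmetric_params(0.5, 0.2, 0.6), seed = 21)
  d <- d[d$reference == "primary", ]
  spec <- model_spec("symmetric_sdt")
  base <- log_likelihood(d, spec, symmetric_params(0.5, 0.2, 0.6))
  for (t in c(-1, -0.1, 0.1, 1, 3)) {
    expect_equal(
      log_likelihood(d, spec, symmetric_params(0.5 + t, 0.2 + t, 0.6)),
      base, tolerance = 1e-12)
  }
})

test_that("the optimizer objective agrees with the reference likelihood", {
  d <- simulate_group(experiment1_design(),
                      params = symmetric_params(0.4, -0.2, 0.5), seed = 31)
  cells <- choicebias:::aggregate_trials(d)
  set.seed(13)
  specs <- list(
    model_spec("symmetric_sdt", n_sigmas = 2, lapse_structure = "four"),
    model_spec("symmetric_sdt", lapse_structure = "one"),
    model_spec("indecision"),
    model_spec("indecision", indecision_bounds = "symmetric")
  )
  for (spec in specs) {
    nm <- choicebias:::free_par_names(spec)
    b <- choicebias:::par_bounds(nm)
    obj <- choicebias:::make_objective(spec, cells)
    for (i in 1:5) {
      v <- b$lo + runif(length(nm)) * (b$hi - b$lo) * 0.4 + 0.01
      names(v) <- nm
      expect_equal(obj(unname(v)), log_likelihood(cells, spec, v),
                   tolerance = 1e-10)
    }
  }
})

test_that("fitting is deterministic and recovers noise-free parameters", {
  gen <- symmetric_params(delta_s = 0, delta_d = 0, sigma_primary = 0.5)
  d <- simulate_group(design_spec(n_per_level = 400), params = gen, seed = 41)
  f1 <- fit_mle(d, model_spec("symmetric_sdt"), seed = 5)
  f2 <- fit_mle(d, model_spec("symmetric_sdt"), seed = 5)
  expect_identical(f1$free, f2$free)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_true(f1$converged)
  expect_lt(abs(f1$estimates$delta_s), 0.08)
  expect_lt(abs(f1$estimates$delta_d), 0.08)
  expect_lt(abs(f1$estimates$sigma_primary - 0.5), 0.05)
  # AIC bookkeeping
  expect_equal(f1$aic, 2 * f1$n_parameters - 2 * f1$log_likelihood)
})

test_that("simulated-data estimates track the generating parameters", {
  d <- simulate_group(experiment1_design(),
                      params = symmetric_params(0.8, -0.3, 0.6), seed = 1)
  f <- fit_mle(d, model_spec("symmetric_sdt"), seed = 1)
  expect_lt(abs(f$estimates$delta_s - 0.8), 0.2)
  expect_lt(abs(f$estimates$delta_d + 0.3), 0.2)
  # the optimum cannot fall below the generating parameters
  gen_ll <- log_likelihood(d, f$spec, symmetric_params(0.8, -0.3, 0.6))
  expect_gte(f$log_likelihood, gen_ll - 1e-6)
})

test_that("the interval model's parameters are recoverable", {
  gen <- asymmetric_params(delta_s = 0.8, delta_d = -0.3,
                           half_width_primary = 1, sigma = 0.5)
  d <- simulate_group(experiment1_design(task = "asymmetric"),
                      params = gen, seed = 17)
  f <- fit_mle(d, model_spec("asymmetric_interval"), seed = 2)
  expect_true(f$converged)
  expect_lt(abs(f$estimates$delta_s - 0.8), 0.2)
  expect_lt(abs(f$estimates$delta_d + 0.3), 0.2)
  expect_lt(abs(f$estimates$half_width_primary - 1), 0.25)
})

test_that("nested structures never lose likelihood to their reductions", {
  d <- simulate_group(experiment1_design(),
                      params = symmetric_params(0.5, 0.3, 0.5, lam1 = 0.05,
                                                lam2 = 0.05, lam1p = 0.05,
                                                lam2p = 0.05),
                      seed = 51)
  chain <- list(
    model_spec("symmetric_sdt", lapse_structure = "none", fixed_lapse = 0.01),
    model_spec("symmetric_sdt", lapse_structure = "one"),
    model_spec("symmetric_sdt", lapse_structure = "two"),
    model_spec("symmetric_sdt", lapse_structure = "four"),
    model_spec("symmetric_sdt", n_sigmas = 2, lapse_structure = "four")
  )
  lls <- numeric(length(chain))
  prev <- NULL
  for (i in seq_along(chain)) {
    f <- fit_mle(d, chain[[i]], seed = 3,
                 extra_start = if (!is.null(prev)) prev$estimates)
    lls[i] <- f$log_likelihood
    prev <- f
  }
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("degenerate responses trigger the weak-identification warning", {
  gen <- symmetric_params(delta_s = -30, sigma_primary = 0.3)
  # all responses identical on both sides (saturated far from the levels)
  d <- simulate_group(design_spec(n_per_level = 5), params = gen, seed = 61)
  w <- testthat::capture_warnings(fit_mle(d, model_spec("symmetric_sdt"),
                                          seed = 1))
  expect_true(length(w) >= 2)  # one per saturated mapping
  expect_true(all(grepl("identical", w)))
})

test_that("trial tables survive a CSV round trip", {
  d <- simulate_group(experiment1_design(),
                      params = symmetric_params(0.3, 0, 0.5), seed = 71)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path), add = TRUE)
  write_trials(d, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(d))
  bad <- tempfile(fileext = ".csv")
  on.exit(unlink(bad), add = TRUE)
  writeLines("a,b\n1,2", bad)
  expect_error(read_trials(bad), "columns")
})

test_that("empty or multi-group tables are rejected", {
  d <- simulate_group(experiment1_design(),
                      params = symmetric_params(), seed = 81)
  expect_error(log_likelihood(d[0, ], model_spec("symmetric_sdt"),
                              symmetric_params()), "empty")
  d2 <- d
  d2$participant <- rep(c("a", "b"), length.out = nrow(d2))
  expect_error(fit_mle(d2, model_spec("symmetric_sdt")), "one group")
})
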