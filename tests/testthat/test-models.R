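test_that("symmetric choice probability matches the cumulative-normal core", {
  # crossing point: at theta = delta_d - delta_s the probability is 1/2
  p <- symmetric_params(delta_s = 0.7, delta_d = -0.2, sigma_primary = 0.4)
  expect_equal(p_choice_symmetric(-0.9, p, "primary"), 0.5)

  # value checked against a CDF oracle built by numerical integration
  p2 <- symmetric_params(delta_s = 0.5, delta_d = 0.25, sigma_primary = 0.5)
  expect_equal(p_choice_symmetric(1, p2, "primary"), oracle_norm_cdf(2.5),
               tolerance = 1e-8)

  # without a decisional bias the two mappings coincide
  p3 <- symmetric_params(delta_s = 1.2, delta_d = 0, sigma_primary = 0.6)
  th <- seq(-3, 3, 0.25)
  expect_equal(p_choice_symmetric(th, p3, "primary"),
               p_choice_symmetric(th, p3, "mirrored"))
})

test_that("lapse rates set the asymptotes of the symmetric model", {
  p <- symmetric_params(sigma_primary = 0.5, lam1 = 0.07, lam2 = 0.12,
                        lam1p = 0.03, lam2p = 0.2)
  expect_equal(p_choice_symmetric(-1e6, p, "primary"), 0.07)
  expect_equal(p_choice_symmetric(1e6, p, "primary"), 1 - 0.12)
  expect_equal(p_choice_symmetric(-1e6, p, "mirrored"), 0.03)
  expect_equal(p_choice_symmetric(1e6, p, "mirrored"), 1 - 0.2)

  # the asymmetric diagnostic lapse loads opposite asymptotes per mapping
  ps <- symmetric_params(sigma_primary = 0.5, lam1 = 0.05, lam2 = 0.05,
                         lam1p = 0.05, lam2p = 0.05, lam_star = 0.1)
  expect_equal(p_choice_symmetric(-1e6, ps, "primary"), 0.15)
  expect_equal(p_choice_symmetric(1e6, ps, "primary"), 0.95)
  expect_equal(p_choice_symmetric(-1e6, ps, "mirrored"), 0.05)
  expect_equal(p_choice_symmetric(1e6, ps, "mirrored"), 0.85)
})

test_that("indecision model composes normal masses with the guess weight", {
  # symmetric bounds and even guessing are neutral at theta = delta_s
  p <- indecision_params(delta_s = 0.4, tau1 = -0.8, tau2 = 0.8, xi = 0.5)
  expect_equal(p_choice_indecision(0.4, p, "primary"), 0.5)

  # empty uncertainty interval reduces to the plain detection-theory form
  p2 <- indecision_params(delta_s = 0.2, tau1 = 0.5, tau2 = 0.5, xi = 0.77,
                          sigma = 0.6)
  th <- seq(-2, 2, 0.4)
  expect_equal(p_choice_indecision(th, p2, "primary"),
               pnorm((th - 0.2 - 0.5) / 0.6))

  # composed value against the CDF oracle
  p3 <- indecision_params(delta_s = 0, tau1 = -0.5, tau2 = 0.5, xi = 0.25,
                          sigma = 1)
  expect_equal(p_choice_indecision(0, p3, "primary"),
               oracle_norm_cdf(-0.5) +
                 0.25 * (oracle_norm_cdf(0.5) - oracle_norm_cdf(-0.5)),
               tolerance = 1e-8)

  # mirrored mapping swaps the guess weight
  expect_equal(p_choice_indecision(0, p3, "mirrored"),
               pnorm(-0.5) + 0.75 * (pnorm(0.5) - pnorm(-0.5)))
})

test_that("interval model peaks at its centre with the stated height", {
  # pure sensory bias: both mappings identical, maximum at delta_s
  p <- asymmetric_params(delta_s = 0.6, delta_d = 0, half_width_primary = 1,
                         sigma = 0.5)
  th <- seq(-3, 3, 0.1)
  expect_equal(p_aligned_asymmetric(th, p, "primary"),
               p_aligned_asymmetric(th, p, "mirrored"))
  expect_equal(th[which.max(p_aligned_asymmetric(th, p, "primary"))], 0.6)

  # unequal half-widths: same peak location, one curve dominates
  p2 <- asymmetric_params(delta_s = 0.6, delta_d = 0,
                          half_width_primary = 1.4,
                          half_width_mirrored = 0.7, sigma = 0.5)
  cp <- p_aligned_asymmetric(th, p2, "primary")
  cm <- p_aligned_asymmetric(th, p2, "mirrored")
  expect_equal(th[which.max(cp)], th[which.max(cm)])
  expect_true(all(cp >= cm))

  # peak height against the CDF oracle
  p3 <- asymmetric_params(half_width_primary = 1, sigma = 1)
  expect_equal(p_aligned_asymmetric(0, p3, "primary"),
               2 * oracle_norm_cdf(1) - 1, tolerance = 1e-8)
})

test_that("probabilities stay in [0, 1] over random valid parameters", {
  set.seed(7)
  th <- seq(-6, 6, 0.5)
  for (i in 1:50) {
    ps <- random_symmetric_params()
    for (s in c("primary", "mirrored")) {
      pr <- p_choice_symmetric(th, ps, s)
      expect_true(all(pr >= 0 & pr <= 1))
      expect_true(all(diff(pr) >= -1e-12))  # nondecreasing in theta
    }
    t1 <- runif(1, -2, 1); t2 <- t1 + runif(1, 0, 2)
    pi_ <- indecision_params(delta_s = runif(1, -2, 2), tau1 = t1, tau2 = t2,
                             xi = runif(1), sigma = runif(1, 0.2, 2))
    pa <- asymmetric_params(delta_s = runif(1, -2, 2),
                            delta_d = runif(1, -1, 1),
                            half_width_primary = runif(1, 0.2, 2),
                            half_width_mirrored = runif(1, 0.2, 2),
                            sigma = runif(1, 0.2, 2),
                            lam1 = runif(1, 0, 0.2), lam2 = runif(1, 0, 0.2),
                            lam1p = runif(1, 0, 0.2),
                            lam2p = runif(1, 0, 0.2))
    for (s in c("primary", "mirrored")) {
      expect_true(all(dplyr::between(p_choice_indecision(th, pi_, s), 0, 1)))
      expect_true(all(dplyr::between(p_aligned_asymmetric(th, pa, s), 0, 1)))
    }
  }
})

test_that("mirror identity links the two mappings through the criterion sign", {
  set.seed(11)
  th <- seq(-4, 4, 0.25)
  for (i in 1:20) {
    ds <- runif(1, -2, 2); dd <- runif(1, -1.5, 1.5); sg <- runif(1, 0.2, 2)
    l1 <- runif(1, 0, 0.2); l2 <- runif(1, 0, 0.2)
    a <- symmetric_params(ds, dd, sg, sg, lam1 = l1, lam2 = l2,
                          lam1p = l1, lam2p = l2)
    b <- symmetric_params(ds, -dd, sg, sg, lam1 = l1, lam2 = l2,
                          lam1p = l1, lam2p = l2)
    expect_equal(p_choice_symmetric(th, a, "primary"),
                 p_choice_symmetric(th, b, "mirrored"))
  }
})

test_that("even guessing with symmetric bounds gives point symmetry", {
  p <- indecision_params(delta_s = 0.8, tau1 = -0.6, tau2 = 0.6, xi = 0.5,
                         sigma = 0.7)
  x <- seq(0, 3, 0.2)
  expect_equal(p_choice_indecision(0.8 + x, p, "primary") +
                 p_choice_indecision(0.8 - x, p, "primary"),
               rep(1, length(x)))
})

test_that("interval-model area is invariant to the decisional shift", {
  th <- seq(-30, 30, 0.01)
  area <- function(dd, side) {
    p <- asymmetric_params(delta_s = 0.3, delta_d = dd,
                           half_width_primary = 1.1, sigma = 0.6)
    sum(p_aligned_asymmetric(th, p, side)) * 0.01
  }
  for (side in c("primary", "mirrored")) {
    a0 <- area(0, side)
    expect_equal(area(0.5, side), a0, tolerance = 1e-6)
    expect_equal(area(-1, side), a0, tolerance = 1e-6)
  }
})

test_that("invalid parameters are rejected with the violated constraint named", {
  expect_error(symmetric_params(sigma_primary = 0), "sigma")
  expect_error(symmetric_params(lam1 = 0.5), "lapse")
  expect_error(symmetric_params(lam1 = 0.45, lam2 = 0.45, lam_star = 0.2),
               "sum")
  expect_error(indecision_params(tau1 = 1, tau2 = -1), "tau1")
  expect_error(indecision_params(xi = 1.2), "xi")
  expect_error(asymmetric_params(half_width_primary = -1), "half-width")
  expect_error(
    indecision_params(tau1 = -1, tau2 = 0.5, symmetric_bounds = TRUE),
    "symmetric")
})
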