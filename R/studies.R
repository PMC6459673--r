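#' Simulation studies validating the estimation and selection pipeline
#'
#' These functions run the package's standard calibration studies on
#' synthetic data from [simulate_group()] / [simulate_population()]: how
#' accurately the joint fit recovers the generating biases, how often the
#' classifier assigns bias labels to unbiased observers (specificity) and to
#' genuinely biased ones (sensitivity), how the AIC comparison between the
#' signal-detection and indecision accounts behaves on detection-theory
#' data, and whether the asymmetric-lapse diagnostic stays at its nominal
#' rejection rate when biases are pure criterion shifts.  All draws are
#' governed by `seed`; study sizes are arguments with the package's standard
#' values as defaults.
#'
#' @param n_groups Number of simulated groups.
#' @param seed Integer master seed.
#' @param design A [design_spec()]; the default is the standard intermixed
#'   constant-stimuli design (9 levels, 30 trials per level per mapping).
#' @param n_starts Multi-starts per fit.
#' @return A tibble with one row per group; see each function's details.
#' @name validation-studies
NULL

#' @describeIn validation-studies Parameter recovery under the basic model:
#'   generating biases drawn from the magnitudes typical of human observers
#'   (sensory up to 1.5 deg, decisional up to 0.5 deg, slope 0.3 to 1.0 deg,
#'   no lapses), each group fitted with the basic three-parameter structure.
#'   Columns: generating and estimated `delta_s`, `delta_d`, `sigma`.
#' @export
study_parameter_recovery <- function(n_groups = 100, seed = 1L,
                                     design = experiment1_design(),
                                     n_starts = 8L) {
  pop <- population_spec(n_groups, lapse_probs = c(none = 1),
                         seed = derive_seed(seed, 1L))
  sim <- simulate_population(pop, design)
  rows <- lapply(seq_len(n_groups), function(i) {
    tr <- sim$truth[i, ]
    g <- sim$trials[sim$trials$participant == tr$participant, ]
    f <- fit_mle(g, model_spec("symmetric_sdt"),
                 seed = derive_seed(seed, 1000L + i), n_starts = n_starts)
    tibble::tibble(
      participant = tr$participant,
      delta_s = tr$delta_s, delta_d = tr$delta_d, sigma = tr$sigma,
      delta_s_hat = f$estimates$delta_s,
      delta_d_hat = f$estimates$delta_d,
      sigma_hat = f$estimates$sigma_primary,
      converged = f$converged
    )
  })
  dplyr::bind_rows(rows)
}

#' @describeIn validation-studies Label rates under a fixed generating bias
#'   pair: every group is generated with the given `delta_s`, `delta_d` and
#'   `sigma` (no lapses) and classified.  Columns: group, assigned `label`,
#'   logical `any_sensory` / `any_decisional`.  With both biases at 0 this
#'   measures specificity; with one bias nonzero, sensitivity.
#' @param delta_s,delta_d,sigma Generating parameters shared by all groups.
#' @param alpha Significance level for selection and classification.
#' @export
study_classification_rates <- function(n_groups = 100, delta_s = 0,
                                       delta_d = 0, sigma = 0.5,
                                       seed = 1L, alpha = 0.05,
                                       design = experiment1_design(),
                                       n_starts = 8L) {
  params <- symmetric_params(delta_s = delta_s, delta_d = delta_d,
                             sigma_primary = sigma)
  rows <- lapply(seq_len(n_groups), function(i) {
    g <- simulate_group(design, params, seed = derive_seed(seed, 2000L + i),
                        participant = sprintf("g%03d", i))
    cb <- classify_bias(g, alpha = alpha,
                        seed = derive_seed(seed, 3000L + i),
                        n_starts = n_starts)
    tibble::tibble(
      participant = sprintf("g%03d", i),
      label = cb$label,
      any_sensory = cb$label %in% c("sensory", "sensory_plus_decisional"),
      any_decisional = cb$label %in% c("decisional",
                                       "sensory_plus_decisional")
    )
  })
  dplyr::bind_rows(rows)
}

#' @describeIn validation-studies AIC comparison against the indecision
#'   model on data from the basic (lapse-free) detection-theory model with
#'   genuine criterion shifts: decisional-bias magnitudes 0.2 to 0.8 deg
#'   with random sign, sensory bias and slope from the population defaults.
#'   Columns: the three AICs and logical `sdt_beats_full` /
#'   `sdt_beats_symmetric` (AIC preference at the comparison resolution of
#'   [compare_indecision()]).
#' @export
study_indecision_comparison <- function(n_groups = 50, seed = 1L,
                                        design = experiment1_design(),
                                        n_starts = 8L) {
  pop <- population_spec(n_groups, delta_d_range = c(0.2, 0.8),
                         lapse_probs = c(none = 1),
                         seed = derive_seed(seed, 2L))
  sim <- simulate_population(pop, design)
  signs <- with_seed(derive_seed(seed, 3L),
                     sample(c(-1, 1), n_groups, replace = TRUE))
  rows <- lapply(seq_len(n_groups), function(i) {
    tr <- sim$truth[i, ]
    params <- symmetric_params(
      delta_s = tr$delta_s, delta_d = signs[i] * tr$delta_d,
      sigma_primary = tr$sigma,
      lam1 = tr$lam_primary, lam2 = tr$lam_primary,
      lam1p = tr$lam_mirrored, lam2p = tr$lam_mirrored)
    g <- simulate_group(design, params,
                        seed = derive_seed(seed, 4000L + i),
                        participant = tr$participant)
    gs <- derive_seed(seed, 5000L + i)
    sel <- select_structure(g, seed = gs, n_starts = n_starts)
    ic <- compare_indecision(g, seed = gs, n_starts = n_starts,
                             selection = sel)
    tibble::tibble(
      participant = tr$participant,
      aic_sdt = ic$aic$aic[1],
      aic_indecision_full = ic$aic$aic[2],
      aic_indecision_symmetric = ic$aic$aic[3],
      sdt_beats_full = aic_prefers_reference(ic$aic, "indecision_full"),
      sdt_beats_symmetric = aic_prefers_reference(ic$aic,
                                                  "indecision_symmetric")
    )
  })
  dplyr::bind_rows(rows)
}

#' @describeIn validation-studies Calibration of the asymmetric-lapse
#'   diagnostic on criterion-shift data: groups generated with nonzero
#'   decisional bias and no asymmetric lapse; the diagnostic should reject
#'   at about its nominal level.  Columns: `p_value`, logical `rejected`.
#' @export
study_lambda_star_calibration <- function(n_groups = 100, seed = 1L,
                                          alpha = 0.05,
                                          design = experiment1_design(),
                                          n_starts = 8L) {
  pop <- population_spec(n_groups, delta_d_range = c(0.2, 0.8),
                         lapse_probs = c(none = 1),
                         seed = derive_seed(seed, 4L))
  sim <- simulate_population(pop, design)
  signs <- with_seed(derive_seed(seed, 5L),
                     sample(c(-1, 1), n_groups, replace = TRUE))
  rows <- lapply(seq_len(n_groups), function(i) {
    tr <- sim$truth[i, ]
    params <- symmetric_params(delta_s = tr$delta_s,
                               delta_d = signs[i] * tr$delta_d,
                               sigma_primary = tr$sigma)
    g <- simulate_group(design, params,
                        seed = derive_seed(seed, 6000L + i),
                        participant = tr$participant)
    step <- lambda_star_check(g, seed = derive_seed(seed, 7000L + i),
                              alpha = alpha, n_starts = n_starts)
    tibble::tibble(participant = tr$participant,
                   p_value = step$p_value,
                   rejected = step$p_value < alpha)
  })
  dplyr::bind_rows(rows)
}

# Exact two-sided binomial acceptance interval (as proportions) around
# probability p at confidence 1 - level, for n trials.
exact_binomial_band <- function(n, p, level = 0.01) {
  stats::qbinom(c(level / 2, 1 - level / 2), n, p) / n
}
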