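#' Likelihood-ratio test between two nested fitted structures
#'
#' Computes twice the log-likelihood difference, refers it to a chi-squared
#' distribution with degrees of freedom equal to the parameter-count
#' difference, and records which structure survives at level `alpha` (the
#' fuller one if and only if the test rejects).  A raw statistic below
#' -1e-6 signals an optimizer failure on the fuller model and is an error.
#'
#' @param full,reduced `fit_result` objects on identical data, with
#'   `reduced$spec` nested in `full$spec`.
#' @param alpha Significance level.
#' @return A `ladder_step` list: `full_spec`, `reduced_spec`,
#'   `lr_statistic`, `df`, `p_value`, `kept`.
#' @export
likelihood_ratio_test <- function(full, reduced, alpha = 0.05) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  if (!is_nested(reduced$spec, full$spec)) {
    stop("reduced spec is not nested in the full spec", call. = FALSE)
  }
  df <- full$n_parameters - reduced$n_parameters
  if (df <= 0) stop("full spec must have more parameters than the reduced",
                    call. = FALSE)
  raw <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (raw < -1e-6) {
    stop("negative likelihood-ratio statistic (", format(raw),
         "): optimizer failed on the fuller model", call. = FALSE)
  }
  stat <- max(raw, 0)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(
    list(full_spec = full$spec, reduced_spec = reduced$spec,
         lr_statistic = stat, df = df, p_value = p,
         kept = if (p < alpha) "full" else "reduced"),
    class = "ladder_step"
  )
}

#' @export
print.ladder_step <- function(x, ...) {
  cat("<ladder_step> LR = ", format(x$lr_statistic, digits = 5),
      ", df = ", x$df, ", p = ", format(x$p_value, digits = 4),
      " -> keep ", x$kept, "\n", sep = "")
  invisible(x)
}

#' Tabulate a trail of ladder steps
#'
#' @param trail A named list of `ladder_step`s, as found in the `$trail`
#'   element of a [classify_bias()] result.
#' @return A tibble with one row per step.
#' @export
trail_table <- function(trail) {
  tibble::tibble(
    step = names(trail) %||% as.character(seq_along(trail)),
    lr_statistic = vapply(trail, `[[`, 0, "lr_statistic"),
    df = vapply(trail, function(s) as.double(s$df), 0),
    p_value = vapply(trail, `[[`, 0, "p_value"),
    kept = vapply(trail, `[[`, "", "kept")
  )
}

# A fuller model can come out a hair below a nested reduction when both stop
# at finite optimizer tolerance.  Before testing, re-polish the fuller fit
# warm-started from the reduction's estimates; the refit can only improve it.
polish_against <- function(full, reduced, cells, seed) {
  if (full$log_likelihood >= reduced$log_likelihood - 1e-12) return(full)
  ref <- fit_mle(cells, full$spec, seed = seed, n_starts = 1L,
                 control = list(factr = 1e2, maxit = 1000L),
                 extra_start = reduced$estimates)
  if (ref$log_likelihood >= reduced$log_likelihood) {
    ref$ladder <- full$ladder
    return(ref)
  }
  # last resort: the reduction's solution is itself a point of the fuller
  # family; adopting it caps the deficit at exactly zero
  emb_free <- params_to_free(full$spec, reduced$estimates)
  emb <- full
  emb$free <- emb_free
  emb$estimates <- free_to_params(full$spec, emb_free)
  emb$log_likelihood <- log_likelihood(cells, full$spec, emb$estimates)
  emb$aic <- 2 * emb$n_parameters - 2 * emb$log_likelihood
  if (emb$log_likelihood >= full$log_likelihood) emb else full
}

# Ladder of structure reductions: resolve lapses first (four -> two -> one ->
# none fixed at 0.01), then the slope (two slopes -> one).  Lapse structure
# distorts slope estimates more than the reverse, so it is settled first.
#' Select the simplest adequate model structure for one group
#'
#' Starting from the fullest joint structure (two slopes, four lapse rates,
#' both biases free), applies consecutive likelihood-ratio tests at level
#' `alpha`, accepting each reduction whose test does not reject: lapse
#' structure is reduced first (four to two to one to none, the last with
#' lapses pinned at 0.01), then the two-slope feature.  The surviving
#' structure always retains free sensory bias, decisional bias and slope.
#'
#' @param trials Trial tibble for exactly one group.
#' @param family `"symmetric_sdt"` or `"asymmetric_interval"`.
#' @param seed Integer seed for the underlying multi-start fits.
#' @param alpha Significance level of each reduction test.
#' @param n_starts Multi-starts per fit.
#' @return The `fit_result` of the selected structure, with the reduction
#'   trail in `$ladder` (a named list of `ladder_step`s).
#' @export
select_structure <- function(trials, family = c("symmetric_sdt",
                                                "asymmetric_interval"),
                             seed = 1L, alpha = 0.05, n_starts = 8L) {
  family <- match.arg(family)
  cells <- aggregate_trials(trials)
  fit1 <- function(spec, i, warm = NULL) {
    f <- fit_mle(cells, spec, seed = derive_seed(seed, i),
                 n_starts = n_starts, extra_start = warm)
    if (!f$converged) {
      stop("model-selection ladder: fit failed to converge for structure ",
           spec$lapse_structure, "/", spec$n_sigmas, " slopes", call. = FALSE)
    }
    f
  }
  current_spec <- model_spec(family, n_sigmas = 2, lapse_structure = "four")
  current <- fit1(current_spec, 1L)
  trail <- list()
  lapse_chain <- c("two", "one", "none")
  i <- 2L
  for (ls in lapse_chain) {
    red_spec <- model_spec(family, n_sigmas = current$spec$n_sigmas,
                           lapse_structure = ls,
                           fixed_lapse = if (ls == "none") 0.01 else 0)
    red <- fit1(red_spec, i, warm = current$estimates); i <- i + 1L
    current <- polish_against(current, red, cells, derive_seed(seed, 50L + i))
    step <- likelihood_ratio_test(current, red, alpha)
    trail[[paste0("lapse_", current$spec$lapse_structure, "_to_", ls)]] <- step
    if (step$kept == "full") break
    current <- red
  }
  red_spec <- model_spec(family, n_sigmas = 1,
                         lapse_structure = current$spec$lapse_structure,
                         fixed_lapse = current$spec$fixed_lapse)
  red <- fit1(red_spec, i, warm = current$estimates)
  current <- polish_against(current, red, cells, derive_seed(seed, 60L))
  step <- likelihood_ratio_test(current, red, alpha)
  trail[["two_slopes_to_one"]] <- step
  if (step$kept == "reduced") current <- red
  current$ladder <- trail
  current
}

#' Classify a group's choice bias as sensory, decisional, both, or none
#'
#' From the structure selected by [select_structure()], tests the three bias
#' reductions by likelihood-ratio test at level `alpha`: decisional bias
#' fixed at 0, sensory bias fixed at 0, and both fixed at 0.  A reduction
#' "provides a better fit" when the test fails to reject it.  The label is
#' `sensory` when only the decisional-bias-free reduction is acceptable,
#' `decisional` when only the sensory-bias-free one is, `no_bias` when both
#' biases can be dropped, and `sensory_plus_decisional` when neither single
#' reduction is acceptable.  If both single reductions are individually
#' acceptable but the double reduction is rejected, the tie is broken by AIC.
#'
#' @inheritParams select_structure
#' @param family `"symmetric_sdt"` or `"asymmetric_interval"`.
#' @param selection Optionally, a precomputed [select_structure()] result for
#'   the same trials and seed.
#' @return A `bias_classification` list: `label`, `selected_spec`,
#'   `delta_s_hat`, `delta_d_hat`, the selected `fit`, and the full test
#'   `trail`.
#' @export
classify_bias <- function(trials, family = c("symmetric_sdt",
                                             "asymmetric_interval"),
                          alpha = 0.05, seed = 1L, n_starts = 8L,
                          selection = NULL) {
  family <- match.arg(family)
  cells <- aggregate_trials(trials)
  if (is.null(selection)) {
    selection <- select_structure(cells, family, seed = seed, alpha = alpha,
                                  n_starts = n_starts)
  }
  sp <- selection$spec
  reduce_fit <- function(bias, i) {
    spec <- model_spec(family, n_sigmas = sp$n_sigmas,
                       lapse_structure = sp$lapse_structure,
                       bias_structure = bias, fixed_lapse = sp$fixed_lapse)
    fit_mle(cells, spec, seed = derive_seed(seed, 100L + i),
            n_starts = n_starts, extra_start = selection$estimates)
  }
  fit_sens <- reduce_fit("sensory_only", 1L)     # delta_d = 0
  fit_dec <- reduce_fit("decisional_only", 2L)   # delta_s = 0
  selection <- polish_against(selection, fit_sens, cells,
                              derive_seed(seed, 111L))
  selection <- polish_against(selection, fit_dec, cells,
                              derive_seed(seed, 112L))
  step_sens <- likelihood_ratio_test(selection, fit_sens, alpha)
  step_dec <- likelihood_ratio_test(selection, fit_dec, alpha)
  trail <- c(selection$ladder,
             list(drop_decisional = step_sens, drop_sensory = step_dec))
  acc_sens <- step_sens$kept == "reduced"
  acc_dec <- step_dec$kept == "reduced"
  if (acc_sens && acc_dec) {
    fit_none <- reduce_fit("none", 3L)
    selection <- polish_against(selection, fit_none, cells,
                                derive_seed(seed, 113L))
    step_none <- likelihood_ratio_test(selection, fit_none, alpha)
    trail$drop_both <- step_none
    label <- if (step_none$kept == "reduced") {
      "no_bias"
    } else if (fit_sens$aic <= fit_dec$aic) {
      "sensory"
    } else {
      "decisional"
    }
  } else if (acc_sens) {
    label <- "sensory"
  } else if (acc_dec) {
    label <- "decisional"
  } else {
    label <- "sensory_plus_decisional"
  }
  structure(
    list(label = label,
         selected_spec = sp,
         delta_s_hat = selection$estimates$delta_s,
         delta_d_hat = selection$estimates$delta_d,
         fit = selection,
         trail = trail),
    class = "bias_classification"
  )
}

#' @export
print.bias_classification <- function(x, ...) {
  cat("<bias_classification> ", x$label,
      " | delta_s = ", format(x$delta_s_hat, digits = 4),
      " | delta_d = ", format(x$delta_d_hat, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Diagnostic test for a stimulus-independent key preference
#'
#' Tests, by likelihood-ratio test, whether adding the asymmetric lapse
#' parameter (an extra lapse on opposite asymptotes for the two reference
#' mappings, i.e. a tendency to press one key regardless of the stimulus) to
#' the two-slope model with one shared lapse rate per mapping improves the
#' fit.  With four fully free asymptote lapses the asymmetric lapse would be
#' unidentifiable, which is why the per-mapping structure hosts it.  A genuine
#' criterion shift is not mimicked by this parameter, so for data generated
#' with a decisional bias and no key preference the test should reject at
#' about the nominal rate.  Diagnostic only; never part of classification.
#'
#' @inheritParams select_structure
#' @return A `ladder_step` comparing the four-lapse structure with and
#'   without the asymmetric lapse.
#' @export
lambda_star_check <- function(trials, seed = 1L, alpha = 0.05,
                              n_starts = 8L) {
  cells <- aggregate_trials(trials)
  base <- fit_mle(cells,
                  model_spec("symmetric_sdt", n_sigmas = 2,
                             lapse_structure = "two"),
                  seed = derive_seed(seed, 201L), n_starts = n_starts)
  star <- fit_mle(cells,
                  model_spec("symmetric_sdt", n_sigmas = 2,
                             lapse_structure = "two_plus_star"),
                  seed = derive_seed(seed, 202L), n_starts = n_starts,
                  extra_start = base$estimates)
  star <- polish_against(star, base, cells, derive_seed(seed, 203L))
  likelihood_ratio_test(star, base, alpha)
}

#' Compare the signal-detection account with the indecision model
#'
#' Fits (i) the structure selected for the group by [select_structure()]
#' under the signal-detection model, (ii) the free-criteria indecision model
#' and (iii) its symmetric-bounds reduction, and compares them by AIC.  When
#' the selected structure is the lapse-free one, its lapses are refitted at
#' exactly zero: the 0.01 pinning applies only to comparisons against lapsed
#' structures inside the selection ladder, not here.  AIC values are compared
#' at a resolution of 1e-6 (differences below the optimizer's own tolerance
#' are not meaningful); the lowest wins, with ties going first to the model
#' with fewer parameters and then to the signal-detection reference model.
#'
#' @inheritParams select_structure
#' @param selection Optionally, a precomputed [select_structure()] result.
#' @return A list with `aic` (tibble of model, log-likelihood, parameters,
#'   AIC), `winner`, and the three fits.
#' @export
compare_indecision <- function(trials, seed = 1L, n_starts = 8L,
                               selection = NULL) {
  cells <- aggregate_trials(trials)
  if (is.null(selection)) {
    selection <- select_structure(cells, "symmetric_sdt", seed = seed,
                                  n_starts = n_starts)
  }
  sdt_fit <- selection
  if (selection$spec$lapse_structure == "none" &&
      selection$spec$fixed_lapse != 0) {
    spec0 <- model_spec("symmetric_sdt", n_sigmas = selection$spec$n_sigmas,
                        lapse_structure = "none", fixed_lapse = 0)
    sdt_fit <- fit_mle(cells, spec0, seed = derive_seed(seed, 303L),
                       n_starts = n_starts,
                       extra_start = selection$estimates)
  }
  ind_full <- fit_mle(cells, model_spec("indecision"),
                      seed = derive_seed(seed, 301L), n_starts = n_starts)
  ind_sym <- fit_mle(cells,
                     model_spec("indecision", indecision_bounds = "symmetric"),
                     seed = derive_seed(seed, 302L), n_starts = n_starts)
  fits <- list(sdt = sdt_fit, indecision_full = ind_full,
               indecision_symmetric = ind_sym)
  aic_tab <- tibble::tibble(
    model = names(fits),
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    n_parameters = vapply(fits, function(f) as.double(f$n_parameters), 0),
    aic = vapply(fits, `[[`, 0, "aic")
  )
  ord <- order(round(aic_tab$aic, 6), aic_tab$n_parameters)
  list(aic = aic_tab, winner = aic_tab$model[ord[1]], fits = fits)
}

# AIC preference between the reference (first) row and another row of a
# compare_indecision table, at the table's comparison resolution.
aic_prefers_reference <- function(aic_tab, model) {
  d <- round(aic_tab$aic[aic_tab$model == model] - aic_tab$aic[1], 6)
  d > 0 || (d == 0 && aic_tab$n_parameters[aic_tab$model == model] >=
              aic_tab$n_parameters[1])
}
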