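#' Declare a model structure for fitting and model selection
#'
#' A `model_spec` names one member of the model family that can be fitted
#' jointly to the two reference mappings of a group: which probability model
#' (`family`), whether the two mappings share a slope (`n_sigmas`; for the
#' interval model this governs the two half-widths instead, the slope itself
#' being shared), how lapse rates are structured, and which bias parameters
#' are free.
#'
#' @param family `"symmetric_sdt"` (cumulative-normal discrimination model),
#'   `"asymmetric_interval"` (aligned/not-aligned interval judgment) or
#'   `"indecision"` (high-threshold guessing model).
#' @param n_sigmas 1 or 2: shared or side-specific slope (half-width for the
#'   interval family). Ignored by the indecision family.
#' @param lapse_structure `"none"` (lapses fixed at `fixed_lapse`), `"one"`
#'   (a single shared lapse rate), `"two"` (one per reference mapping),
#'   `"four"` (one per asymptote), or `"two_plus_star"` (one per mapping plus
#'   the asymmetric diagnostic lapse, which loads the lower asymptote of the
#'   primary-mapping curve and the upper asymptote of the mirrored one;
#'   with four free lapses the diagnostic lapse would be redundant).
#' @param bias_structure `"full"` (sensory and decisional bias free),
#'   `"sensory_only"` (decisional bias fixed at 0), `"decisional_only"`
#'   (sensory bias fixed at 0) or `"none"` (both fixed at 0).
#' @param fixed_lapse Value at which all lapse rates are pinned when
#'   `lapse_structure = "none"`.  0 by default; the model-selection ladder
#'   uses 0.01 when comparing against lapsed structures, which fits real
#'   choice data better than exactly zero asymptotes.
#' @param indecision_bounds For the indecision family only: `"free"` (both
#'   criteria free; 5 parameters) or `"symmetric"` (criteria constrained to
#'   `tau1 = -tau2`; 4 parameters).
#' @return An object of class `model_spec`.
#' @examples
#' basic <- model_spec("symmetric_sdt")
#' n_parameters(basic)  # delta_s, delta_d, sigma
#' @export
model_spec <- function(family = c("symmetric_sdt", "asymmetric_interval",
                                  "indecision"),
                       n_sigmas = 1,
                       lapse_structure = c("none", "one", "two", "four",
                                           "two_plus_star"),
                       bias_structure = c("full", "sensory_only",
                                          "decisional_only", "none"),
                       fixed_lapse = 0,
                       indecision_bounds = c("free", "symmetric")) {
  family <- match.arg(family)
  lapse_structure <- match.arg(lapse_structure)
  bias_structure <- match.arg(bias_structure)
  indecision_bounds <- match.arg(indecision_bounds)
  stopifnot(n_sigmas %in% c(1, 2),
            fixed_lapse >= 0, fixed_lapse < 0.5)
  if (family == "indecision" && lapse_structure != "none") {
    stop("the indecision family carries no lapse parameters", call. = FALSE)
  }
  if (family == "asymmetric_interval" && lapse_structure == "two_plus_star") {
    stop("the asymmetric diagnostic lapse is defined for the symmetric ",
         "family only", call. = FALSE)
  }
  structure(
    list(family = family, n_sigmas = as.integer(n_sigmas),
         lapse_structure = lapse_structure, bias_structure = bias_structure,
         fixed_lapse = fixed_lapse, indecision_bounds = indecision_bounds),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$family,
      " | bias: ", x$bias_structure,
      " | slopes: ", x$n_sigmas,
      " | lapses: ", x$lapse_structure,
      if (x$lapse_structure == "none") paste0(" (fixed ", x$fixed_lapse, ")"),
      if (x$family == "indecision") paste0(" | bounds: ", x$indecision_bounds),
      " | k = ", n_parameters(x), "\n", sep = "")
  invisible(x)
}

n_lapse_params <- function(lapse_structure) {
  switch(lapse_structure,
         none = 0L, one = 1L, two = 2L, four = 4L, two_plus_star = 3L)
}

n_bias_params <- function(bias_structure) {
  switch(bias_structure,
         full = 2L, sensory_only = 1L, decisional_only = 1L, none = 0L)
}

#' Number of parameters of a model structure
#'
#' Counts the parameters the structure estimates; this is the count used for
#' likelihood-ratio degrees of freedom and AIC.  The free-criteria indecision
#' model counts 5 parameters (sensory bias, slope, two criteria, guess
#' probability) even though the sensory bias and the two criteria share a flat
#' direction of the likelihood; see the methods vignette.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count.
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$family,
    symmetric_sdt =
      n_bias_params(spec$bias_structure) + spec$n_sigmas +
        n_lapse_params(spec$lapse_structure),
    asymmetric_interval =
      n_bias_params(spec$bias_structure) + 1L + spec$n_sigmas +
        n_lapse_params(spec$lapse_structure),
    indecision =
      if (spec$indecision_bounds == "free") 5L else 4L
  )
}

#' Test whether one model structure is nested in another
#'
#' @param reduced,full [model_spec()] objects of the same family.
#' @return `TRUE` when every distribution expressible under `reduced` is
#'   expressible under `full`.
#' @export
is_nested <- function(reduced, full) {
  stopifnot(inherits(reduced, "model_spec"), inherits(full, "model_spec"))
  if (reduced$family != full$family) return(FALSE)
  if (reduced$family == "indecision") {
    return(reduced$indecision_bounds == "symmetric" ||
             full$indecision_bounds == "free")
  }
  lapse_rank <- c(none = 0, one = 1, two = 2, two_plus_star = 2.5, four = 3)
  bias_free <- list(full = c("s", "d"), sensory_only = "s",
                    decisional_only = "d", none = character())
  all(bias_free[[reduced$bias_structure]] %in%
        bias_free[[full$bias_structure]]) &&
    reduced$n_sigmas <= full$n_sigmas &&
    lapse_rank[[reduced$lapse_structure]] <= lapse_rank[[full$lapse_structure]]
}

# --- free-parameter bookkeeping -------------------------------------------
# Each spec maps to a named vector of free parameters with box bounds; the
# optimizer works on a logit-transformed unconstrained scale.

par_bounds <- function(name) {
  lo <- c(delta_s = -10, delta_d = -10,
          sigma_primary = 0.05, sigma_mirrored = 0.05, sigma = 0.05,
          half_width_primary = 0.05, half_width_mirrored = 0.05,
          lam = 0, lam_primary = 0, lam_mirrored = 0,
          lam1 = 0, lam2 = 0, lam1p = 0, lam2p = 0, lam_star = 0,
          xi = 0, tau1 = -10, tau_gap = 0, tau = 0)
  hi <- c(delta_s = 10, delta_d = 10,
          sigma_primary = 10, sigma_mirrored = 10, sigma = 10,
          half_width_primary = 10, half_width_mirrored = 10,
          lam = 0.45, lam_primary = 0.45, lam_mirrored = 0.45,
          lam1 = 0.45, lam2 = 0.45, lam1p = 0.45, lam2p = 0.45,
          lam_star = 0.45,
          xi = 1, tau1 = 10, tau_gap = 20, tau = 10)
  list(lo = unname(lo[name]), hi = unname(hi[name]))
}

free_par_names <- function(spec) {
  bias <- switch(spec$bias_structure,
                 full = c("delta_s", "delta_d"),
                 sensory_only = "delta_s",
                 decisional_only = "delta_d",
                 none = character())
  lapse <- switch(spec$lapse_structure,
                  none = character(),
                  one = "lam",
                  two = c("lam_primary", "lam_mirrored"),
                  two_plus_star = c("lam_primary", "lam_mirrored", "lam_star"),
                  four = c("lam1", "lam2", "lam1p", "lam2p"))
  switch(spec$family,
    symmetric_sdt = c(
      bias,
      if (spec$n_sigmas == 2) c("sigma_primary", "sigma_mirrored")
      else "sigma_primary",
      lapse),
    asymmetric_interval = c(
      bias, "sigma",
      if (spec$n_sigmas == 2) c("half_width_primary", "half_width_mirrored")
      else "half_width_primary",
      lapse),
    indecision =
      if (spec$indecision_bounds == "free") {
        # delta_s is absorbed by the criteria (flat likelihood direction)
        # and fixed at 0 during optimization; see n_parameters().
        c("tau1", "tau_gap", "xi", "sigma")
      } else {
        c("delta_s", "tau", "xi", "sigma")
      }
  )
}

# Expand a named free-parameter vector into the family's full parameter object.
free_to_params <- function(spec, v) {
  g <- function(name, default = 0) if (name %in% names(v)) v[[name]] else default
  switch(spec$family,
    symmetric_sdt = {
      lam <- switch(spec$lapse_structure,
        none = rep(spec$fixed_lapse, 4),
        one = rep(g("lam"), 4),
        two = ,
        two_plus_star = c(g("lam_primary"), g("lam_primary"),
                          g("lam_mirrored"), g("lam_mirrored")),
        four = c(g("lam1"), g("lam2"), g("lam1p"), g("lam2p")))
      symmetric_params(
        delta_s = g("delta_s"), delta_d = g("delta_d"),
        sigma_primary = g("sigma_primary", 1),
        sigma_mirrored = if (spec$n_sigmas == 2) g("sigma_mirrored", 1)
                         else g("sigma_primary", 1),
        lam1 = lam[1], lam2 = lam[2], lam1p = lam[3], lam2p = lam[4],
        lam_star = g("lam_star"))
    },
    asymmetric_interval = {
      lam <- switch(spec$lapse_structure,
        none = rep(spec$fixed_lapse, 4),
        one = rep(g("lam"), 4),
        two = c(g("lam_primary"), g("lam_primary"),
                g("lam_mirrored"), g("lam_mirrored")),
        four = c(g("lam1"), g("lam2"), g("lam1p"), g("lam2p")))
      asymmetric_params(
        delta_s = g("delta_s"), delta_d = g("delta_d"),
        half_width_primary = g("half_width_primary", 1),
        half_width_mirrored = if (spec$n_sigmas == 2)
          g("half_width_mirrored", 1) else g("half_width_primary", 1),
        sigma = g("sigma", 1),
        lam1 = lam[1], lam2 = lam[2], lam1p = lam[3], lam2p = lam[4])
    },
    indecision = {
      if (spec$indecision_bounds == "free") {
        indecision_params(delta_s = 0,
                          tau1 = g("tau1"),
                          tau2 = g("tau1") + g("tau_gap"),
                          xi = g("xi", 0.5), sigma = g("sigma", 1))
      } else {
        indecision_params(delta_s = g("delta_s"),
                          tau1 = -g("tau", 1), tau2 = g("tau", 1),
                          xi = g("xi", 0.5), sigma = g("sigma", 1),
                          symmetric_bounds = TRUE)
      }
    }
  )
}

# Extract a spec's free-parameter vector from a full parameter object of the
# same family (used to warm-start a fit from a nested fit's estimates).
params_to_free <- function(spec, params) {
  nm <- free_par_names(spec)
  take <- function(name) {
    switch(name,
           delta_s = params$delta_s,
           delta_d = params$delta_d,
           sigma_primary = params$sigma_primary,
           sigma_mirrored = params$sigma_mirrored,
           sigma = params$sigma,
           half_width_primary = params$half_width_primary,
           half_width_mirrored = params$half_width_mirrored,
           lam = params$lam1,
           lam_primary = params$lam1,
           lam_mirrored = params$lam1p,
           lam1 = params$lam1, lam2 = params$lam2,
           lam1p = params$lam1p, lam2p = params$lam2p,
           lam_star = params$lam_star %||% 0,
           xi = params$xi,
           # the free-criteria variant absorbs delta_s into the criteria
           tau1 = params$tau1 + params$delta_s,
           tau_gap = params$tau2 - params$tau1,
           tau = params$tau2)
  }
  v <- vapply(nm, take, 0)
  names(v) <- nm
  v
}

# Model probability for one reference side given a spec and free vector.
spec_prob <- function(spec, params, theta, side) {
  switch(spec$family,
         symmetric_sdt = p_choice_symmetric(theta, params, side),
         asymmetric_interval = p_aligned_asymmetric(theta, params, side),
         indecision = p_choice_indecision(theta, params, side))
}

to_unconstrained <- function(v, lo, hi) {
  z <- (v - lo) / (hi - lo)
  stats::qlogis(pmin(pmax(z, 1e-7), 1 - 1e-7))
}

from_unconstrained <- function(u, lo, hi) {
  lo + (hi - lo) * stats::plogis(u)
}
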