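#' Constant-stimuli design specification
#'
#' Describes one group's stimulus design: the signed orientation levels, the
#' number of trials per level and reference mapping, the task and the
#' orientation band.  The defaults reproduce the design under which the
#' models here are normally exercised: 9 levels from -2 to 2 deg in 0.5 deg
#' steps with 30 trials per level per reference mapping (270 trials per
#' psychometric function).
#'
#' @param levels Strictly increasing signed orientations, degrees.
#' @param n_per_level Trials per level per reference mapping.
#' @param task `"symmetric"` or `"asymmetric"`.
#' @param orientation_band `"horizontal"` or `"vertical"`.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(levels = seq(-2, 2, by = 0.5), n_per_level = 30,
                        task = c("symmetric", "asymmetric"),
                        orientation_band = c("horizontal", "vertical")) {
  task <- match.arg(task)
  orientation_band <- match.arg(orientation_band)
  stopifnot(length(levels) > 0, !is.unsorted(levels, strictly = TRUE),
            n_per_level >= 1)
  structure(
    list(levels = as.numeric(levels), n_per_level = as.integer(n_per_level),
         task = task, orientation_band = orientation_band),
    class = "design_spec"
  )
}

#' @rdname design_spec
#' @details `experiment1_design()` is the default intermixed design
#'   (6 blocks of 360 trials shared over 8 intermixed conditions gives 30
#'   trials per cell); `experiment2_design()` is the blocked variant with the
#'   same per-cell count, symmetric task only, vertical orientations
#'   (4 blocks of 270 trials, two reference mappings).
#' @export
experiment1_design <- function(task = c("symmetric", "asymmetric"),
                               orientation_band = c("horizontal",
                                                    "vertical")) {
  design_spec(task = match.arg(task),
              orientation_band = match.arg(orientation_band))
}

#' @rdname design_spec
#' @export
experiment2_design <- function() {
  design_spec(task = "symmetric", orientation_band = "vertical")
}

#' Simulate one group of trials under a model
#'
#' For every (level, reference-mapping) cell of the design, draws Bernoulli
#' responses with the probability given by the model for those parameters,
#' then shuffles the trial order deterministically.  Repeated calls with the
#' same arguments return an identical table.
#'
#' @param design A [design_spec()].
#' @param params A [symmetric_params()], [asymmetric_params()] or
#'   [indecision_params()] object; the model family follows the class.
#' @param seed Integer seed.
#' @param participant Participant identifier for the output table.
#' @return A trial tibble with columns `participant`, `task`,
#'   `orientation_band`, `reference`, `orientation_deg`, `response`.
#' @examples
#' d <- simulate_group(experiment1_design(),
#'                     params = symmetric_params(delta_s = 1, sigma_primary = 0.5),
#'                     seed = 42)
#' table(d$reference, d$orientation_deg)
#' @export
simulate_group <- function(design, params, seed, participant = "g01") {
  stopifnot(inherits(design, "design_spec"))
  validate_params(params)
  family <- switch(class(params)[1],
                   symmetric_params = "symmetric_sdt",
                   asymmetric_params = "asymmetric_interval",
                   indecision_params = "indecision")
  spec <- model_spec(family)
  grid <- expand.grid(reference = c("primary", "mirrored"),
                      orientation_deg = design$levels,
                      stringsAsFactors = FALSE)
  theta <- rep(grid$orientation_deg, each = design$n_per_level)
  side <- rep(grid$reference, each = design$n_per_level)
  p <- numeric(length(theta))
  for (s in c("primary", "mirrored")) {
    idx <- side == s
    p[idx] <- spec_prob(spec, params, theta[idx], s)
  }
  resp <- with_seed(seed, {
    r <- stats::rbinom(length(p), 1L, p)
    ord <- sample.int(length(p))
    list(r = r[ord], theta = theta[ord], side = side[ord])
  })
  tibble::tibble(
    participant = participant,
    task = design$task,
    orientation_band = design$orientation_band,
    reference = resp$side,
    orientation_deg = resp$theta,
    response = resp$r
  )
}

#' Population specification for simulation studies
#'
#' Describes a population of groups with generating parameters drawn
#' uniformly from the given ranges.  The default ranges span the bias
#' magnitudes typical of human observers in cardinal-orientation judgments
#' (sensory biases up to about 1.5 deg, decisional biases a few times
#' smaller) and the default lapse-structure mix matches the relative
#' frequencies with which the lapse variants are needed in practice
#' (most groups none, then one, two, four shared lapse parameters).
#'
#' @param n_groups Number of groups.
#' @param delta_s_range,delta_d_range,sigma_range Uniform ranges for the
#'   generating sensory bias, decisional bias and slope (degrees).
#' @param lapse_probs Named probabilities over lapse structures
#'   (`none`, `one`, `two`, `four`).
#' @param lapse_range Uniform range for any nonzero generating lapse rate.
#' @param seed Mandatory integer seed.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_groups,
                            delta_s_range = c(-1.5, 1.5),
                            delta_d_range = c(-0.5, 0.5),
                            sigma_range = c(0.3, 1.0),
                            lapse_probs = c(none = 20, one = 7,
                                            two = 4, four = 3) / 34,
                            lapse_range = c(0.02, 0.1),
                            seed) {
  if (missing(seed)) stop("a seed is mandatory for a population_spec",
                          call. = FALSE)
  stopifnot(n_groups >= 0,
            all(names(lapse_probs) %in% c("none", "one", "two", "four")))
  structure(
    list(n_groups = as.integer(n_groups),
         delta_s_range = delta_s_range, delta_d_range = delta_d_range,
         sigma_range = sigma_range,
         lapse_probs = lapse_probs / sum(lapse_probs),
         lapse_range = lapse_range,
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

implied_bias_label <- function(delta_s, delta_d, tol = 1e-12) {
  s <- abs(delta_s) > tol
  d <- abs(delta_d) > tol
  if (s && d) "sensory_plus_decisional"
  else if (s) "sensory"
  else if (d) "decisional"
  else "no_bias"
}

#' Simulate a population of groups plus its ground truth
#'
#' Draws generating parameters per group from the population ranges, then
#' simulates each group's trials under the symmetric-task model.  The
#' returned truth table records every generating parameter and the bias
#' label implied by the generating biases, for parameter-recovery and
#' classification-calibration studies.
#'
#' @param pop A [population_spec()].
#' @param design A [design_spec()] shared by all groups.
#' @return A list with `trials` (all groups concatenated) and `truth`
#'   (one row per group).
#' @export
simulate_population <- function(pop, design = experiment1_design()) {
  stopifnot(inherits(pop, "population_spec"),
            inherits(design, "design_spec"))
  ng <- pop$n_groups
  if (ng == 0) {
    return(list(
      trials = simulate_group(design, symmetric_params(), seed = 1)[0, ],
      truth = tibble::tibble(participant = character(), delta_s = numeric(),
                             delta_d = numeric(), sigma = numeric(),
                             lapse_structure = character(), lam = numeric(),
                             lam_primary = numeric(), lam_mirrored = numeric(),
                             true_label = character())
    ))
  }
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  truth <- with_seed(pop$seed, {
    rows <- lapply(seq_len(ng), function(i) {
      structure_i <- sample(names(pop$lapse_probs), 1,
                            prob = pop$lapse_probs)
      lam <- if (structure_i == "none") 0 else runif1(pop$lapse_range)
      lam_m <- if (structure_i %in% c("two", "four")) {
        runif1(pop$lapse_range)
      } else {
        lam
      }
      tibble::tibble(
        participant = sprintf("g%03d", i),
        delta_s = runif1(pop$delta_s_range),
        delta_d = runif1(pop$delta_d_range),
        sigma = runif1(pop$sigma_range),
        lapse_structure = structure_i,
        lam = lam, lam_primary = lam, lam_mirrored = lam_m
      )
    })
    dplyr::bind_rows(rows)
  })
  truth$true_label <- mapply(implied_bias_label, truth$delta_s, truth$delta_d)
  trials <- dplyr::bind_rows(lapply(seq_len(ng), function(i) {
    tr <- truth[i, ]
    params <- symmetric_params(
      delta_s = tr$delta_s, delta_d = tr$delta_d,
      sigma_primary = tr$sigma,
      lam1 = tr$lam_primary, lam2 = tr$lam_primary,
      lam1p = tr$lam_mirrored, lam2p = tr$lam_mirrored
    )
    simulate_group(design, params, seed = derive_seed(pop$seed, i),
                   participant = tr$participant)
  }))
  list(trials = trials, truth = truth)
}
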