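#' Read a trial table from delimited text
#'
#' Expects a comma-separated file with a header row and the columns
#' `participant`, `task`, `orientation_band`, `reference`, `orientation_deg`,
#' `response` (optionally `block`).  `reference` must be `"primary"` or
#' `"mirrored"` (recode raw right/left or top/bottom references before
#' loading), `response` strictly 0/1.
#'
#' @param path Path to a CSV file.
#' @return A tibble of trials.
#' @export
read_trials <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trials(tab)
  tab
}

#' Write a trial table to delimited text
#'
#' @param trials A trial tibble as produced by [simulate_group()].
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

validate_trials <- function(trials) {
  need <- c("participant", "task", "orientation_band", "reference",
            "orientation_deg", "response")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials)) {
    if (!all(trials$reference %in% c("primary", "mirrored"))) {
      stop("reference must be 'primary' or 'mirrored'", call. = FALSE)
    }
    if (!all(trials$response %in% c(0, 1))) {
      stop("response must be strictly binary (0/1)", call. = FALSE)
    }
    if (!all(is.finite(trials$orientation_deg))) {
      stop("orientation_deg must be finite", call. = FALSE)
    }
  }
  invisible(trials)
}

# Collapse the trials of one group into binomial cells (reference x level).
# Constant-stimuli designs repeat exact levels, so cells are formed by exact
# equality after rounding orientations to 1e-6 deg.  Cells are sorted so
# downstream results are invariant to the row order of the input.
aggregate_trials <- function(trials) {
  if (inherits(trials, "trial_cells")) return(trials)
  validate_trials(trials)
  if (!nrow(trials)) stop("empty trial table", call. = FALSE)
  key <- unique(trials[c("participant", "orientation_band", "task")])
  if (nrow(key) > 1) {
    stop("trial table must contain exactly one group ",
         "(participant x orientation_band x task)", call. = FALSE)
  }
  tab <- tibble::tibble(
    side = trials$reference,
    theta = round(trials$orientation_deg * 1e6) / 1e6,
    response = trials$response
  )
  tab <- dplyr::summarise(dplyr::group_by(tab, .data$side, .data$theta),
                          k = sum(.data$response), n = dplyr::n(),
                          .groups = "drop")
  ord <- order(match(tab$side, c("primary", "mirrored")), tab$theta)
  structure(
    list(side = tab$side[ord], theta = tab$theta[ord],
         k = tab$k[ord], n = tab$n[ord],
         key = key),
    class = "trial_cells"
  )
}

cell_probs <- function(spec, params, cells) {
  p <- numeric(length(cells$theta))
  for (s in c("primary", "mirrored")) {
    idx <- cells$side == s
    if (any(idx)) p[idx] <- spec_prob(spec, params, cells$theta[idx], s)
  }
  p
}

#' Joint log-likelihood of a model structure on one group's trials
#'
#' Sums, over the binomial cells of the two reference mappings, the full
#' binomial log-probability (including the binomial coefficient) of the
#' observed choice counts under the model's choice probabilities.  Cell
#' probabilities are clipped to `[1e-10, 1 - 1e-10]` for numerical safety.
#'
#' @param trials Trial tibble for exactly one group.
#' @param spec A [model_spec()].
#' @param params A parameter object valid for the spec's family, or a named
#'   vector of the spec's free parameters.
#' @return Log-likelihood in nats.
#' @export
log_likelihood <- function(trials, spec, params) {
  cells <- aggregate_trials(trials)
  if (!inherits(params, c("symmetric_params", "asymmetric_params",
                          "indecision_params"))) {
    params <- free_to_params(spec, params)
  }
  p <- cell_probs(spec, params, cells)
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  sum(stats::dbinom(cells$k, cells$n, p, log = TRUE))
}

# Empirical probit start values for one side's cells; NULL when degenerate.
side_probit_start <- function(cells, s) {
  idx <- cells$side == s
  if (!any(idx)) return(NULL)
  th <- cells$theta[idx]; k <- cells$k[idx]; n <- cells$n[idx]
  if (length(unique(th)) < 2) return(NULL)
  fit <- tryCatch(
    suppressWarnings(stats::glm(cbind(k, n - k) ~ th,
                                family = stats::binomial("probit"))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  b <- stats::coef(fit)
  if (!all(is.finite(b)) || b[2] <= 1e-3) return(NULL)
  list(center = unname(-b[1] / b[2]), sigma = unname(1 / b[2]))
}

# Data-derived start values (natural scale) for every free parameter.
start_values <- function(spec, cells) {
  sp <- side_probit_start(cells, "primary")
  sm <- side_probit_start(cells, "mirrored")
  cp <- if (!is.null(sp)) sp$center else 0
  cm <- if (!is.null(sm)) sm$center else 0
  sig_vals <- c(if (!is.null(sp)) sp$sigma, if (!is.null(sm)) sm$sigma)
  sig <- if (length(sig_vals)) stats::median(sig_vals) else 1
  sig <- min(max(sig, 0.1), 5)
  cp <- min(max(cp, -5), 5); cm <- min(max(cm, -5), 5)
  nm <- free_par_names(spec)
  v <- numeric(length(nm)); names(v) <- nm
  if (spec$family == "asymmetric_interval") {
    # peak of the aligned-probability curve per side
    peak <- function(s) {
      idx <- cells$side == s
      if (!any(idx)) return(0)
      pr <- cells$k[idx] / cells$n[idx]
      min(max(cells$theta[idx][which.max(pr)], -5), 5)
    }
    mp <- peak("primary"); mm <- peak("mirrored")
    defaults <- c(delta_s = (mp + mm) / 2, delta_d = (mp - mm) / 2,
                  sigma = 0.5, half_width_primary = 1,
                  half_width_mirrored = 1,
                  lam = 0.01, lam_primary = 0.01, lam_mirrored = 0.01,
                  lam1 = 0.01, lam2 = 0.01, lam1p = 0.01, lam2p = 0.01)
  } else if (spec$family == "indecision") {
    c0 <- (cp + cm) / 2
    defaults <- c(delta_s = c0, tau1 = c0 - sig, tau_gap = 2 * sig,
                  tau = sig, xi = 0.5, sigma = sig)
  } else {
    defaults <- c(delta_s = -(cp + cm) / 2, delta_d = (cp - cm) / 2,
                  sigma_primary = sig, sigma_mirrored = sig,
                  lam = 0.01, lam_primary = 0.01, lam_mirrored = 0.01,
                  lam1 = 0.01, lam2 = 0.01, lam1p = 0.01, lam2p = 0.01,
                  lam_star = 0.005)
  }
  for (name in nm) v[[name]] <- defaults[[name]]
  v
}

# Deterministic jitter scales for multi-start perturbation, per parameter.
start_jitter_scale <- function(name) {
  base <- c(delta_s = 0.5, delta_d = 0.3, sigma = 0.4, sigma_primary = 0.4,
            sigma_mirrored = 0.4, half_width_primary = 0.5,
            half_width_mirrored = 0.5, lam = 0.04, lam_primary = 0.04,
            lam_mirrored = 0.04, lam1 = 0.04, lam2 = 0.04, lam1p = 0.04,
            lam2p = 0.04, lam_star = 0.03, xi = 0.25, tau1 = 0.75,
            tau_gap = 0.75, tau = 0.5)
  unname(base[name])
}

#' Fit a model structure to one group by maximum likelihood
#'
#' Maximizes [log_likelihood()] over the free parameters of `spec` by
#' box-constrained quasi-Newton search (L-BFGS-B with numerical gradients;
#' a bounded simplex search is the fallback if the line search fails),
#' restarted from several deterministic, seed-derived start points built
#' around empirical probit estimates of each mapping's crossing point and
#' slope.  The best converged optimum is returned.
#'
#' @param trials Trial tibble for exactly one group (both reference mappings
#'   present for joint structures).
#' @param spec A [model_spec()].
#' @param seed Integer seed governing the multi-start perturbations.
#' @param n_starts Number of start points (first is unperturbed).
#' @param control Optional list: `maxit` (iterations per start, default
#'   500) and `factr` (L-BFGS-B relative tolerance factor, default 1e6,
#'   i.e. about 2e-10 relative).
#' @param extra_start Optional warm start: a named free-parameter vector or
#'   a parameter object of the spec's family (e.g. the estimates of a fit
#'   this spec is nested in), appended to the start set.
#' @return A `fit_result` with elements `spec`, `estimates` (full parameter
#'   object), `free` (named free-parameter vector), `log_likelihood`,
#'   `n_parameters`, `aic`, `converged`, `n_restarts_used` and a per-start
#'   table `starts`.
#' @examples
#' d <- simulate_group(experiment1_design(),
#'                     params = symmetric_params(delta_s = 0.8,
#'                                               delta_d = -0.3,
#'                                               sigma_primary = 0.6),
#'                     seed = 1)
#' fit <- fit_mle(d, model_spec("symmetric_sdt"), seed = 1)
#' fit$estimates$delta_s
#' @export
fit_mle <- function(trials, spec, seed = 1L, n_starts = 8L, control = list(),
                    extra_start = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  cells <- aggregate_trials(trials)
  maxit <- control$maxit %||% 500L
  factr <- control$factr %||% 1e6

  for (s in c("primary", "mirrored")) {
    idx <- cells$side == s
    if (any(idx) &&
        (sum(cells$k[idx]) == 0 || sum(cells$k[idx]) == sum(cells$n[idx]))) {
      warning("all responses identical on the ", s,
              " side; biases are weakly identified", call. = FALSE)
    }
  }

  nm <- free_par_names(spec)
  bounds <- par_bounds(nm)
  base <- start_values(spec, cells)
  eps <- 1e-4
  clampv <- function(v) pmin(pmax(v, bounds$lo + eps * (bounds$hi - bounds$lo)),
                             bounds$hi - eps * (bounds$hi - bounds$lo))

  jit <- with_seed(derive_seed(seed, 1L), {
    matrix(stats::runif(max(n_starts - 1L, 0L) * length(nm), -1, 1),
           ncol = length(nm))
  })
  scales <- start_jitter_scale(nm)
  starts <- vector("list", n_starts)
  starts[[1L]] <- clampv(base)
  if (n_starts > 1L) {
    for (i in 2:n_starts) {
      starts[[i]] <- clampv(base + jit[i - 1L, ] * scales)
    }
  }
  if (!is.null(extra_start)) {
    if (inherits(extra_start, c("symmetric_params", "asymmetric_params",
                                "indecision_params"))) {
      extra_start <- params_to_free(spec, extra_start)
    }
    stopifnot(all(nm %in% names(extra_start)))
    starts[[length(starts) + 1L]] <- clampv(unname(extra_start[nm]))
  }

  objective <- make_objective(spec, cells)

  run_start <- function(v0) {
    out <- tryCatch(
      stats::optim(v0, objective, method = "L-BFGS-B",
                   lower = bounds$lo, upper = bounds$hi,
                   control = list(fnscale = -1, maxit = maxit,
                                  factr = factr)),
      error = function(e) NULL)
    if (is.null(out)) {
      # fallback: bounded simplex on the logit-transformed scale
      obj_u <- function(u) objective(from_unconstrained(u, bounds$lo,
                                                        bounds$hi))
      o <- stats::optim(to_unconstrained(v0, bounds$lo, bounds$hi), obj_u,
                        method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 2000L,
                                       reltol = 1e-9))
      out <- list(par = from_unconstrained(o$par, bounds$lo, bounds$hi),
                  value = o$value, convergence = o$convergence)
    }
    out
  }

  results <- lapply(starts, run_start)
  n_all <- length(results)
  lls <- vapply(results, `[[`, 0, "value")
  # a start stuck in the constraint-penalty region is not a converged fit
  conv <- vapply(results, function(r) r$convergence == 0L, TRUE) &
    is.finite(lls) & lls > -1e9
  start_tab <- tibble::tibble(
    start = seq_len(n_all),
    log_likelihood = lls,
    converged = conv,
    delta_s = NA_real_, delta_d = NA_real_
  )
  for (i in seq_len(n_all)) {
    v <- results[[i]]$par
    names(v) <- nm
    if ("delta_s" %in% nm) start_tab$delta_s[i] <- v[["delta_s"]]
    if ("delta_d" %in% nm) start_tab$delta_d[i] <- v[["delta_d"]]
  }

  pick <- if (any(conv)) which(conv)[which.max(lls[conv])] else which.max(lls)
  v_best <- results[[pick]]$par
  names(v_best) <- nm
  # a start can end at a parameter point the family's validator rejects
  # (e.g. a lapse sum driven against its joint constraint); fall back to the
  # best remaining valid start
  ok <- function(v) !inherits(tryCatch(free_to_params(spec, v),
                                       error = function(e) e), "error")
  if (!ok(v_best)) {
    cand <- order(lls, decreasing = TRUE)
    cand <- cand[vapply(cand, function(i) {
      v <- results[[i]]$par; names(v) <- nm; ok(v)
    }, TRUE)]
    if (!length(cand)) {
      stop("no start produced a valid parameter vector", call. = FALSE)
    }
    pick <- cand[1L]
    v_best <- results[[pick]]$par
    names(v_best) <- nm
    conv[pick] <- conv[pick] && TRUE
  }
  ll <- lls[[pick]]
  k <- n_parameters(spec)
  structure(
    list(spec = spec,
         estimates = free_to_params(spec, v_best),
         free = v_best,
         log_likelihood = ll,
         n_parameters = k,
         aic = 2 * k - 2 * ll,
         converged = any(conv),
         n_restarts_used = n_all,
         starts = start_tab),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$spec$family,
      " | logLik = ", format(x$log_likelihood, digits = 8),
      " | k = ", x$n_parameters,
      " | AIC = ", format(x$aic, digits = 8),
      " | converged: ", x$converged, "\n", sep = "")
  est <- unlist(x$estimates[vapply(x$estimates, is.numeric, TRUE)])
  print(round(est, 4))
  invisible(x)
}

#' Write a collection of fit results to delimited text
#'
#' One row per fit: group keys, model structure, estimates, log-likelihood
#' and AIC.
#'
#' @param fits A list of `fit_result` objects (optionally named by group).
#' @param path Output CSV path.
#' @export
write_fits <- function(fits, path) {
  rows <- lapply(fits, function(f) {
    est <- f$estimates
    tibble::tibble(
      family = f$spec$family,
      bias_structure = f$spec$bias_structure,
      n_sigmas = f$spec$n_sigmas,
      lapse_structure = f$spec$lapse_structure,
      delta_s = est$delta_s %||% NA_real_,
      delta_d = est$delta_d %||% NA_real_,
      log_likelihood = f$log_likelihood,
      n_parameters = f$n_parameters,
      aic = f$aic,
      converged = f$converged
    )
  })
  tab <- dplyr::bind_rows(rows, .id = "group")
  readr::write_csv(tab, path)
  invisible(path)
}
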