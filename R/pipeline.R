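#' Run the full bias analysis over a multi-group trial table
#'
#' Splits the table into groups (participant x orientation band x task),
#' screens each group for usable psychometric modulation, then runs structure
#' selection and bias classification, and — for symmetric-task groups whose
#' label includes a decisional bias — the indecision-model AIC comparison.
#' Per-group failures are recorded and skipped, not fatal.
#'
#' Screening: a group is excluded as `"inverted"` when its empirical choice
#' proportions clearly decrease with orientation (mean Spearman rank trend
#' across the two mappings below -0.5), and as `"not_modulated"` when the basic psychometric model does
#' not beat a flat (intercept-only) binomial model by likelihood-ratio test
#' at level `alpha`, or when the fitted slope escapes to its upper bound.
#'
#' @param trials Trial tibble, any number of groups (may be empty).
#' @param alpha Significance level used for screening, selection and
#'   classification.
#' @param seed Integer master seed; per-group seeds are derived
#'   deterministically from it and the sorted group keys.
#' @param check_indecision Run [compare_indecision()] for symmetric-task
#'   groups with a decisional component in their label.
#' @param n_starts Multi-starts per fit.
#' @return A list of class `bias_analysis`: `classifications` (one row per
#'   analyzed group, with bias estimates, selected structure, single-reference
#'   bias estimates and the test trail as a list column), `status` (one row
#'   per group with inclusion/exclusion and reason), `indecision` (AIC
#'   comparisons, when run).
#' @export
run_dataset <- function(trials, alpha = 0.05, seed = 1L,
                        check_indecision = TRUE, n_starts = 8L) {
  validate_trials(trials)
  empty <- list(
    classifications = tibble::tibble(
      participant = character(), orientation_band = character(),
      task = character(), label = character(), delta_s = numeric(),
      delta_d = numeric(), sigma_primary = numeric(),
      sigma_mirrored = numeric(), n_sigmas = integer(),
      lapse_structure = character(),
      single_ref_bias_primary = numeric(),
      single_ref_bias_mirrored = numeric(),
      trail = list()),
    status = tibble::tibble(
      participant = character(), orientation_band = character(),
      task = character(), included = logical(), reason = character()),
    indecision = tibble::tibble(
      participant = character(), orientation_band = character(),
      task = character(), aic_sdt = numeric(), aic_indecision_full = numeric(),
      aic_indecision_symmetric = numeric(), winner = character())
  )
  if (!nrow(trials)) {
    return(structure(c(empty, list(alpha = alpha, seed = seed)),
                     class = "bias_analysis"))
  }
  keys <- dplyr::distinct(trials, .data$participant, .data$orientation_band,
                          .data$task)
  keys <- dplyr::arrange(keys, .data$participant, .data$orientation_band,
                         .data$task)
  class_rows <- list(); status_rows <- list(); ind_rows <- list()
  for (gi in seq_len(nrow(keys))) {
    key <- keys[gi, ]
    g <- dplyr::semi_join(trials, key,
                          by = c("participant", "orientation_band", "task"))
    gseed <- derive_seed(seed, gi)
    family <- if (key$task == "asymmetric") "asymmetric_interval"
              else "symmetric_sdt"
    scr <- tryCatch(screen_group(g, family, alpha, gseed, n_starts),
                    error = function(e) list(ok = FALSE,
                                             reason = conditionMessage(e)))
    if (!scr$ok) {
      status_rows[[gi]] <- dplyr::mutate(key, included = FALSE,
                                         reason = scr$reason)
      next
    }
    res <- tryCatch({
      cb <- classify_bias(g, family, alpha = alpha, seed = gseed,
                          n_starts = n_starts)
      est <- cb$fit$estimates
      sr <- single_reference_bias(cb$fit)
      row <- dplyr::mutate(
        key,
        label = cb$label,
        delta_s = cb$delta_s_hat, delta_d = cb$delta_d_hat,
        sigma_primary = est$sigma_primary %||% est$sigma,
        sigma_mirrored = est$sigma_mirrored %||% est$sigma,
        n_sigmas = cb$selected_spec$n_sigmas,
        lapse_structure = cb$selected_spec$lapse_structure,
        single_ref_bias_primary = sr["primary"],
        single_ref_bias_mirrored = sr["mirrored"],
        trail = list(cb$trail))
      list(row = row, cb = cb)
    }, error = function(e) NULL)
    if (is.null(res)) {
      status_rows[[gi]] <- dplyr::mutate(key, included = FALSE,
                                         reason = "fit_failed")
      next
    }
    class_rows[[gi]] <- res$row
    status_rows[[gi]] <- dplyr::mutate(key, included = TRUE,
                                       reason = NA_character_)
    if (check_indecision && family == "symmetric_sdt" &&
        res$cb$label %in% c("decisional", "sensory_plus_decisional")) {
      ic <- tryCatch(compare_indecision(g, seed = gseed, n_starts = n_starts,
                                        selection = res$cb$fit),
                     error = function(e) NULL)
      if (!is.null(ic)) {
        ind_rows[[gi]] <- dplyr::mutate(
          key,
          aic_sdt = ic$aic$aic[1],
          aic_indecision_full = ic$aic$aic[2],
          aic_indecision_symmetric = ic$aic$aic[3],
          winner = ic$winner)
      }
    }
  }
  out <- list(
    classifications = if (length(class_rows)) dplyr::bind_rows(class_rows)
                      else empty$classifications,
    status = if (length(status_rows)) dplyr::bind_rows(status_rows)
             else empty$status,
    indecision = if (length(ind_rows)) dplyr::bind_rows(ind_rows)
                 else empty$indecision,
    alpha = alpha, seed = seed
  )
  structure(out, class = "bias_analysis")
}

#' @export
print.bias_analysis <- function(x, ...) {
  cat("<bias_analysis> ", nrow(x$status), " group(s), ",
      sum(x$status$included), " analyzed\n", sep = "")
  if (nrow(x$classifications)) {
    print(dplyr::count(x$classifications, .data$label))
  }
  invisible(x)
}

# Screening against flat / inverted response patterns; see run_dataset().
screen_group <- function(trials, family, alpha, seed, n_starts) {
  cells <- aggregate_trials(trials)
  rho <- vapply(c("primary", "mirrored"), function(s) {
    idx <- cells$side == s
    if (sum(idx) < 3) return(NA_real_)
    suppressWarnings(stats::cor(cells$theta[idx],
                                cells$k[idx] / cells$n[idx],
                                method = "spearman"))
  }, 0)
  if (family == "symmetric_sdt" && all(!is.na(rho)) && mean(rho) < -0.5) {
    return(list(ok = FALSE, reason = "inverted"))
  }
  basic <- fit_mle(cells, model_spec(family), seed = seed,
                   n_starts = n_starts)
  p0 <- sum(cells$k) / sum(cells$n)
  p0 <- min(max(p0, 1e-10), 1 - 1e-10)
  ll_flat <- sum(stats::dbinom(cells$k, cells$n, p0, log = TRUE))
  df <- basic$n_parameters - 1L
  stat <- max(2 * (basic$log_likelihood - ll_flat), 0)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  sigma_hat <- basic$estimates$sigma_primary %||% basic$estimates$sigma
  if (p >= alpha || sigma_hat >= 9.99) {
    return(list(ok = FALSE, reason = "not_modulated"))
  }
  list(ok = TRUE, reason = NA_character_)
}

# Single-reference bias estimates from a fitted model: the orientation of the
# 50% crossing for the discrimination model, the orientation of the maximum
# for the interval model (both computed on the fitted curve, so lapse
# structure is honored).
single_reference_bias <- function(fit) {
  spec <- fit$spec
  est <- fit$estimates
  out <- c(primary = NA_real_, mirrored = NA_real_)
  for (s in c("primary", "mirrored")) {
    out[s] <- if (spec$family == "asymmetric_interval") {
      stats::optimize(function(th) p_aligned_asymmetric(th, est, s),
                      interval = c(-20, 20), maximum = TRUE)$maximum
    } else {
      f <- function(th) spec_prob(spec, est, th, s) - 0.5
      if (f(-20) * f(20) > 0) NA_real_
      else stats::uniroot(f, c(-20, 20), tol = 1e-9)$root
    }
  }
  out
}

#' Summarize bias classifications across groups
#'
#' Produces the group-level summaries used to describe a dataset: per-group
#' rows; the mean and 95% t-interval of the absolute sensory and decisional
#' biases with a paired t-test between them; Pearson correlations of the
#' sensory bias across tasks (symmetric vs asymmetric, within participant and
#' orientation band) and across orientation bands (within participant and
#' task).
#'
#' @param classifications The `classifications` tibble of a [run_dataset()]
#'   result (or any tibble with columns `participant`, `orientation_band`,
#'   `task`, `delta_s`, `delta_d`).
#' @return A list of class `bias_summary`: `per_group`, `aggregate` (NULL if
#'   fewer than 2 rows), `cross_task`, `cross_orientation` (NULL when the
#'   pairing is unavailable).
#' @export
summarize_biases <- function(classifications) {
  cl <- classifications
  out <- list(per_group = cl, aggregate = NULL, cross_task = NULL,
              cross_orientation = NULL)
  if (nrow(cl) >= 2) {
    abs_s <- abs(cl$delta_s); abs_d <- abs(cl$delta_d)
    ci <- function(x) {
      if (stats::sd(x) == 0) c(mean(x), mean(x))
      else as.numeric(stats::t.test(x)$conf.int)
    }
    paired <- if (stats::sd(abs_s - abs_d) == 0) {
      list(statistic = NA_real_, parameter = nrow(cl) - 1, p.value = NA_real_)
    } else {
      stats::t.test(abs_s, abs_d, paired = TRUE)
    }
    out$aggregate <- tibble::tibble(
      n_groups = nrow(cl),
      mean_abs_delta_s = mean(abs_s),
      ci_lo_abs_delta_s = ci(abs_s)[1], ci_hi_abs_delta_s = ci(abs_s)[2],
      mean_abs_delta_d = mean(abs_d),
      ci_lo_abs_delta_d = ci(abs_d)[1], ci_hi_abs_delta_d = ci(abs_d)[2],
      t_paired = as.numeric(paired$statistic),
      df_paired = as.numeric(paired$parameter),
      p_paired = as.numeric(paired$p.value)
    )
  }
  cor_row <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
    ct <- stats::cor.test(x, y)
    tibble::tibble(r = as.numeric(ct$estimate),
                   df = as.numeric(ct$parameter),
                   p_value = ct$p.value, n = length(x))
  }
  if (length(unique(cl$task)) == 2) {
    w <- tidyr::pivot_wider(
      cl[c("participant", "orientation_band", "task", "delta_s")],
      names_from = "task", values_from = "delta_s")
    w <- w[stats::complete.cases(w), ]
    out$cross_task <- cor_row(w$symmetric, w$asymmetric)
  }
  if (length(unique(cl$orientation_band)) == 2) {
    w <- tidyr::pivot_wider(
      cl[c("participant", "task", "orientation_band", "delta_s")],
      names_from = "orientation_band", values_from = "delta_s")
    w <- w[stats::complete.cases(w), ]
    out$cross_orientation <- cor_row(w$horizontal, w$vertical)
  }
  structure(out, class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat("<bias_summary> ", nrow(x$per_group), " group(s)\n", sep = "")
  if (!is.null(x$aggregate)) {
    a <- x$aggregate
    cat(sprintf("  mean |delta_s| = %.3f [%.3f, %.3f]\n",
                a$mean_abs_delta_s, a$ci_lo_abs_delta_s, a$ci_hi_abs_delta_s))
    cat(sprintf("  mean |delta_d| = %.3f [%.3f, %.3f]\n",
                a$mean_abs_delta_d, a$ci_lo_abs_delta_d, a$ci_hi_abs_delta_d))
    cat(sprintf("  paired t(%d) = %.2f, p = %.2g\n",
                a$df_paired, a$t_paired, a$p_paired))
  }
  if (!is.null(x$cross_task)) {
    cat(sprintf("  cross-task r(%d) = %.2f\n", x$cross_task$df,
                x$cross_task$r))
  }
  if (!is.null(x$cross_orientation)) {
    cat(sprintf("  cross-orientation r(%d) = %.2f\n",
                x$cross_orientation$df, x$cross_orientation$r))
  }
  invisible(x)
}

#' Write per-group classifications to delimited text
#'
#' @param analysis A `bias_analysis` from [run_dataset()], or its
#'   `classifications` tibble.
#' @param path Output CSV path.
#' @export
write_classifications <- function(analysis, path) {
  cl <- if (inherits(analysis, "bias_analysis")) analysis$classifications
        else analysis
  if ("trail" %in% names(cl)) {
    cl$trail_p_values <- vapply(cl$trail, function(tr) {
      paste(sprintf("%s=%.4g", names(tr),
                    vapply(tr, `[[`, 0, "p_value")), collapse = ";")
    }, "")
    cl$trail <- NULL
  }
  readr::write_csv(cl, path)
  invisible(path)
}

#' Plot a group's choice data and fitted psychometric curves
#'
#' Empirical per-cell choice proportions (points, one color per reference
#' mapping) with the fitted model curves when a fit is supplied.
#'
#' @param trials Trial tibble for one group.
#' @param fit Optional `fit_result` for the same group.
#' @return A ggplot object.
#' @export
plot_group <- function(trials, fit = NULL) {
  cells <- aggregate_trials(trials)
  df <- tibble::tibble(reference = cells$side, orientation = cells$theta,
                       proportion = cells$k / cells$n)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$orientation, .data$proportion,
                                        colour = .data$reference)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "orientation (deg)", y = "P(choice)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- seq(min(df$orientation), max(df$orientation), length.out = 201)
    curves <- dplyr::bind_rows(lapply(c("primary", "mirrored"), function(s) {
      tibble::tibble(reference = s, orientation = grid,
                     proportion = spec_prob(fit$spec, fit$estimates, grid, s))
    }))
    p <- p + ggplot2::geom_line(data = curves)
  }
  p
}
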