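#' Parameters of the symmetric-task signal-detection psychometric model
#'
#' The symmetric two-alternative task (clockwise vs counterclockwise relative
#' to an imagined reference) is modelled in stimulus space as a cumulative
#' normal whose centre combines a sensory bias \eqn{\delta_S} — a shift of the
#' internal neutral point that moves the curves for both reference mappings in
#' the same direction — and a decisional bias \eqn{\delta_D} — a criterion
#' shift that moves the two curves in opposite directions.  The probability of
#' a clockwise-consistent choice is \eqn{\Phi((\theta - (\delta_D -
#' \delta_S))/\sigma_1)} for the primary reference and \eqn{\Phi((\theta -
#' (-\delta_D - \delta_S))/\sigma_2)} for the mirrored reference, optionally
#' deformed by lapse rates at the asymptotes.
#'
#' @param delta_s Sensory bias, degrees.
#' @param delta_d Decisional bias, degrees.
#' @param sigma_primary Slope (SD of the internal noise in stimulus units) for
#'   the primary reference; strictly positive, degrees.
#' @param sigma_mirrored Slope for the mirrored reference; defaults to
#'   `sigma_primary` (the one-slope model).
#' @param lam1,lam2 Lapse rates on the lower and upper asymptote of the
#'   primary-reference curve, each in `[0, 0.5)`.
#' @param lam1p,lam2p Lapse rates for the mirrored-reference curve.
#' @param lam_star Asymmetric diagnostic lapse: a stimulus-independent
#'   preference for one response key, raising the lower asymptote of the
#'   primary-reference curve and lowering the upper asymptote of the
#'   mirrored-reference curve.  Zero unless the diagnostic variant is fitted.
#' @return An object of class `symmetric_params`.
#' @seealso [p_choice_symmetric()]
#' @export
symmetric_params <- function(delta_s = 0, delta_d = 0,
                             sigma_primary = 1,
                             sigma_mirrored = sigma_primary,
                             lam1 = 0, lam2 = 0, lam1p = 0, lam2p = 0,
                             lam_star = 0) {
  p <- structure(
    list(delta_s = delta_s, delta_d = delta_d,
         sigma_primary = sigma_primary, sigma_mirrored = sigma_mirrored,
         lam1 = lam1, lam2 = lam2, lam1p = lam1p, lam2p = lam2p,
         lam_star = lam_star),
    class = "symmetric_params"
  )
  validate_params(p)
  p
}

#' Parameters of the asymmetric-task interval-judgment model
#'
#' In the asymmetric task the observer reports whether the grating is aligned
#' with the imagined reference.  The model responds "aligned" when the internal
#' orientation estimate falls inside a criterion interval: the interval centre
#' is \eqn{\delta_S + \delta_D} for the primary reference and \eqn{\delta_S -
#' \delta_D} for the mirrored one (an asymmetric decisional bias flips sign
#' with the mapping), while unequal half-widths across sides encode a
#' symmetric decisional bias — a tendency to respond "aligned" more often for
#' one mapping without moving the curve's peak.
#'
#' @param delta_s Sensory bias, degrees.
#' @param delta_d Asymmetric decisional bias (interval-centre shift), degrees.
#' @param half_width_primary,half_width_mirrored Criterion interval
#'   half-widths, degrees, strictly positive.
#' @param sigma Internal noise SD, degrees, strictly positive.
#' @param lam1,lam2,lam1p,lam2p Lapse rates as in [symmetric_params()].
#' @return An object of class `asymmetric_params`.
#' @seealso [p_aligned_asymmetric()]
#' @export
asymmetric_params <- function(delta_s = 0, delta_d = 0,
                              half_width_primary = 1,
                              half_width_mirrored = half_width_primary,
                              sigma = 1,
                              lam1 = 0, lam2 = 0, lam1p = 0, lam2p = 0) {
  p <- structure(
    list(delta_s = delta_s, delta_d = delta_d,
         half_width_primary = half_width_primary,
         half_width_mirrored = half_width_mirrored,
         sigma = sigma,
         lam1 = lam1, lam2 = lam2, lam1p = lam1p, lam2p = lam2p),
    class = "asymmetric_params"
  )
  validate_params(p)
  p
}

#' Parameters of the high-threshold indecision model
#'
#' The indecision model divides the sensory axis into three regions by two
#' criteria: below the lower criterion the observer chooses counterclockwise,
#' above the upper criterion clockwise, and inside the uncertainty interval the
#' observer guesses, choosing the clockwise-consistent alternative with
#' probability `xi` for the primary reference and `1 - xi` for the mirrored
#' one (the criteria themselves do not change with the mapping).  Criteria are
#' expressed in stimulus space (`tau1`, `tau2`, degrees) so that `delta_s` and
#' `sigma` are commensurable with the signal-detection model's.
#'
#' @param delta_s Sensory bias, degrees.
#' @param tau1,tau2 Uncertainty-interval bounds in stimulus space, degrees,
#'   with `tau1 <= tau2`.
#' @param xi Guess probability toward the clockwise-consistent alternative for
#'   the primary reference, in `[0, 1]`.
#' @param sigma Internal noise SD, degrees, strictly positive.
#' @param symmetric_bounds If `TRUE` the reduced variant with `tau1 = -tau2`
#'   is declared; construction then checks that constraint.
#' @return An object of class `indecision_params`.
#' @seealso [p_choice_indecision()]
#' @export
indecision_params <- function(delta_s = 0, tau1 = -1, tau2 = 1, xi = 0.5,
                              sigma = 1, symmetric_bounds = FALSE) {
  p <- structure(
    list(delta_s = delta_s, tau1 = tau1, tau2 = tau2, xi = xi,
         sigma = sigma, symmetric_bounds = symmetric_bounds),
    class = "indecision_params"
  )
  validate_params(p)
  p
}

validate_params <- function(p) UseMethod("validate_params")

#' @export
validate_params.symmetric_params <- function(p) {
  if (p$sigma_primary <= 0 || p$sigma_mirrored <= 0) {
    stop("invalid parameters: sigma must be strictly positive", call. = FALSE)
  }
  lams <- c(p$lam1, p$lam2, p$lam1p, p$lam2p, p$lam_star)
  if (any(lams < 0) || any(lams >= 0.5)) {
    stop("invalid parameters: lapse rates must lie in [0, 0.5)", call. = FALSE)
  }
  if (p$lam1 + p$lam2 + p$lam_star >= 1 ||
      p$lam1p + p$lam2p + p$lam_star >= 1) {
    stop("invalid parameters: lapse rates on one curve must sum to < 1",
         call. = FALSE)
  }
  invisible(p)
}

#' @export
validate_params.asymmetric_params <- function(p) {
  if (p$sigma <= 0) {
    stop("invalid parameters: sigma must be strictly positive", call. = FALSE)
  }
  if (p$half_width_primary <= 0 || p$half_width_mirrored <= 0) {
    stop("invalid parameters: interval half-widths must be strictly positive",
         call. = FALSE)
  }
  lams <- c(p$lam1, p$lam2, p$lam1p, p$lam2p)
  if (any(lams < 0) || any(lams >= 0.5)) {
    stop("invalid parameters: lapse rates must lie in [0, 0.5)", call. = FALSE)
  }
  invisible(p)
}

#' @export
validate_params.indecision_params <- function(p) {
  if (p$sigma <= 0) {
    stop("invalid parameters: sigma must be strictly positive", call. = FALSE)
  }
  if (p$tau1 > p$tau2) {
    stop("invalid parameters: tau1 must not exceed tau2", call. = FALSE)
  }
  if (p$xi < 0 || p$xi > 1) {
    stop("invalid parameters: xi must lie in [0, 1]", call. = FALSE)
  }
  if (isTRUE(p$symmetric_bounds) && abs(p$tau1 + p$tau2) > 1e-8) {
    stop("invalid parameters: symmetric_bounds requires tau1 = -tau2",
         call. = FALSE)
  }
  invisible(p)
}

#' Choice probability under the symmetric-task signal-detection model
#'
#' Probability of the clockwise-consistent choice as a function of signed
#' stimulus orientation, for one reference mapping.  The core is the
#' cumulative normal centred on \eqn{\delta_D - \delta_S} (primary) or
#' \eqn{-\delta_D - \delta_S} (mirrored); the side's lapse transform is then
#' applied, with `lam_star` placed on opposite asymptotes for the two sides.
#'
#' @param theta Signed orientation(s), degrees; vectorised.
#' @param params A [symmetric_params()] object.
#' @param side `"primary"` or `"mirrored"` reference mapping.
#' @return Probabilities in `[0, 1]`, same length as `theta`.
#' @examples
#' p <- symmetric_params(delta_s = 0.5, delta_d = 0.25, sigma_primary = 0.5)
#' p_choice_symmetric(0, p, "primary")
#' @export
p_choice_symmetric <- function(theta, params, side = c("primary", "mirrored")) {
  side <- match_side(side)
  validate_params(params)
  if (side == "primary") {
    core <- stats::pnorm((theta - (params$delta_d - params$delta_s)) /
                           params$sigma_primary)
    params$lam1 + params$lam_star +
      (1 - params$lam1 - params$lam2 - params$lam_star) * core
  } else {
    core <- stats::pnorm((theta - (-params$delta_d - params$delta_s)) /
                           params$sigma_mirrored)
    params$lam1p +
      (1 - params$lam1p - params$lam2p - params$lam_star) * core
  }
}

#' Choice probability under the indecision model
#'
#' With `z = theta - delta_s`, returns
#' \eqn{\Phi((z - \tau_2)/\sigma) + g\,[\Phi((\tau_2 - z)/\sigma) -
#' \Phi((\tau_1 - z)/\sigma)]} where the guess weight `g` is `xi` for the
#' primary reference and `1 - xi` for the mirrored one.
#'
#' @inheritParams p_choice_symmetric
#' @param params An [indecision_params()] object.
#' @return Probabilities in `[0, 1]`, same length as `theta`.
#' @export
p_choice_indecision <- function(theta, params,
                                side = c("primary", "mirrored")) {
  side <- match_side(side)
  validate_params(params)
  z <- theta - params$delta_s
  g <- if (side == "primary") params$xi else 1 - params$xi
  stats::pnorm((z - params$tau2) / params$sigma) +
    g * (stats::pnorm((params$tau2 - z) / params$sigma) -
           stats::pnorm((params$tau1 - z) / params$sigma))
}

#' "Aligned" probability under the asymmetric-task interval model
#'
#' The core is the probability that the internal estimate falls inside the
#' criterion interval, \eqn{\Phi((\theta - (m - h))/\sigma) - \Phi((\theta -
#' (m + h))/\sigma)}, with centre `m = delta_s + delta_d` (primary) or
#' `delta_s - delta_d` (mirrored) and the side's half-width `h`; the side's
#' lapse transform is then applied.  The curve peaks at `theta = m` with
#' pre-lapse height \eqn{2\Phi(h/\sigma) - 1}.
#'
#' @inheritParams p_choice_symmetric
#' @param params An [asymmetric_params()] object.
#' @return Probabilities in `[0, 1]`, same length as `theta`.
#' @export
p_aligned_asymmetric <- function(theta, params,
                                 side = c("primary", "mirrored")) {
  side <- match_side(side)
  validate_params(params)
  if (side == "primary") {
    m <- params$delta_s + params$delta_d
    h <- params$half_width_primary
    l1 <- params$lam1; l2 <- params$lam2
  } else {
    m <- params$delta_s - params$delta_d
    h <- params$half_width_mirrored
    l1 <- params$lam1p; l2 <- params$lam2p
  }
  core <- stats::pnorm((theta - (m - h)) / params$sigma) -
    stats::pnorm((theta - (m + h)) / params$sigma)
  l1 + (1 - l1 - l2) * core
}
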