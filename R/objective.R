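# Fast likelihood closure used by the optimizer.
#
# Builds, for one (spec, cells) pair, a function of the natural-scale free
# parameter vector that returns the joint log-likelihood.  The math is the
# same as log_likelihood() (which is the readable reference path); here the
# per-evaluation overhead is stripped: index masks and the binomial
# coefficients are precomputed, and probabilities are computed inline.
make_objective <- function(spec, cells) {
  nm <- free_par_names(spec)
  iP <- cells$side == "primary"
  iM <- !iP
  thP <- cells$theta[iP]; kP <- cells$k[iP]; nP <- cells$n[iP]
  thM <- cells$theta[iM]; kM <- cells$k[iM]; nM <- cells$n[iM]
  const <- sum(lchoose(cells$n, cells$k))
  idx <- function(name) match(name, nm)
  ll_binom <- function(pP, pM) {
    pP <- pmin(pmax(pP, 1e-10), 1 - 1e-10)
    pM <- pmin(pmax(pM, 1e-10), 1 - 1e-10)
    const + sum(kP * log(pP) + (nP - kP) * log1p(-pP)) +
      sum(kM * log(pM) + (nM - kM) * log1p(-pM))
  }

  if (spec$family == "symmetric_sdt") {
    i_ds <- idx("delta_s"); i_dd <- idx("delta_d")
    i_sp <- idx("sigma_primary"); i_sm <- idx("sigma_mirrored")
    ls <- spec$lapse_structure
    i_lam <- idx("lam")
    i_lp <- idx("lam_primary"); i_lm <- idx("lam_mirrored")
    i_l1 <- idx("lam1"); i_l2 <- idx("lam2")
    i_l1p <- idx("lam1p"); i_l2p <- idx("lam2p"); i_st <- idx("lam_star")
    fx <- spec$fixed_lapse
    function(v) {
      ds <- if (is.na(i_ds)) 0 else v[i_ds]
      dd <- if (is.na(i_dd)) 0 else v[i_dd]
      sp <- v[i_sp]
      sm <- if (is.na(i_sm)) sp else v[i_sm]
      if (ls == "none") {
        l1 <- fx; l2 <- fx; l1p <- fx; l2p <- fx; st <- 0
      } else if (ls == "one") {
        l1 <- v[i_lam]; l2 <- l1; l1p <- l1; l2p <- l1; st <- 0
      } else if (ls == "two") {
        l1 <- v[i_lp]; l2 <- l1; l1p <- v[i_lm]; l2p <- l1p; st <- 0
      } else if (ls == "two_plus_star") {
        l1 <- v[i_lp]; l2 <- l1; l1p <- v[i_lm]; l2p <- l1p; st <- v[i_st]
        s1 <- l1 + l2 + st; s2 <- l1p + l2p + st
        if (s1 >= 0.999 || s2 >= 0.999) {
          return(-1e10 * (1 + max(s1, s2)))
        }
      } else {
        l1 <- v[i_l1]; l2 <- v[i_l2]; l1p <- v[i_l1p]; l2p <- v[i_l2p]
        st <- 0
      }
      pP <- l1 + st + (1 - l1 - l2 - st) * stats::pnorm((thP - (dd - ds)) / sp)
      pM <- l1p + (1 - l1p - l2p - st) * stats::pnorm((thM - (-dd - ds)) / sm)
      ll_binom(pP, pM)
    }
  } else if (spec$family == "asymmetric_interval") {
    i_ds <- idx("delta_s"); i_dd <- idx("delta_d")
    i_sig <- idx("sigma")
    i_hp <- idx("half_width_primary"); i_hm <- idx("half_width_mirrored")
    ls <- spec$lapse_structure
    i_lam <- idx("lam")
    i_lp <- idx("lam_primary"); i_lm <- idx("lam_mirrored")
    i_l1 <- idx("lam1"); i_l2 <- idx("lam2")
    i_l1p <- idx("lam1p"); i_l2p <- idx("lam2p")
    fx <- spec$fixed_lapse
    function(v) {
      ds <- if (is.na(i_ds)) 0 else v[i_ds]
      dd <- if (is.na(i_dd)) 0 else v[i_dd]
      sg <- v[i_sig]
      hp <- v[i_hp]
      hm <- if (is.na(i_hm)) hp else v[i_hm]
      if (ls == "none") {
        l1 <- fx; l2 <- fx; l1p <- fx; l2p <- fx
      } else if (ls == "one") {
        l1 <- v[i_lam]; l2 <- l1; l1p <- l1; l2p <- l1
      } else if (ls == "two") {
        l1 <- v[i_lp]; l2 <- l1; l1p <- v[i_lm]; l2p <- l1p
      } else {
        l1 <- v[i_l1]; l2 <- v[i_l2]; l1p <- v[i_l1p]; l2p <- v[i_l2p]
      }
      mP <- ds + dd; mM <- ds - dd
      coreP <- stats::pnorm((thP - (mP - hp)) / sg) -
        stats::pnorm((thP - (mP + hp)) / sg)
      coreM <- stats::pnorm((thM - (mM - hm)) / sg) -
        stats::pnorm((thM - (mM + hm)) / sg)
      ll_binom(l1 + (1 - l1 - l2) * coreP, l1p + (1 - l1p - l2p) * coreM)
    }
  } else {
    free_bounds <- spec$indecision_bounds == "free"
    i_ds <- idx("delta_s"); i_t1 <- idx("tau1"); i_gap <- idx("tau_gap")
    i_tau <- idx("tau"); i_xi <- idx("xi"); i_sig <- idx("sigma")
    function(v) {
      if (free_bounds) {
        ds <- 0; t1 <- v[i_t1]; t2 <- t1 + v[i_gap]
      } else {
        ds <- v[i_ds]; t1 <- -v[i_tau]; t2 <- v[i_tau]
      }
      xi <- v[i_xi]; sg <- v[i_sig]
      zP <- thP - ds; zM <- thM - ds
      pP <- stats::pnorm((zP - t2) / sg) +
        xi * (stats::pnorm((t2 - zP) / sg) - stats::pnorm((t1 - zP) / sg))
      pM <- stats::pnorm((zM - t2) / sg) +
        (1 - xi) * (stats::pnorm((t2 - zM) / sg) - stats::pnorm((t1 - zM) / sg))
      ll_binom(pP, pM)
    }
  }
}
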