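# Independent numerical oracles, deliberately built from primitives other
# than the code paths they check.

# Standard normal CDF by numerical integration of the density (Simpson rule
# on [-12, x]), independent of pnorm.
oracle_norm_cdf <- function(x) {
  vapply(x, function(xi) {
    lo <- -12
    if (xi <= lo) return(0)
    n <- 4000L
    h <- (xi - lo) / n
    g <- lo + h * (0:n)
    w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
    sum(w * exp(-g^2 / 2)) * h / 3 / sqrt(2 * pi)
  }, 0)
}

# Upper-tail chi-squared probability by numerical integration of the density
# (Simpson rule on [q, q + far]), independent of pchisq.
oracle_chisq_tail <- function(q, df) {
  far <- max(40, q * 4 + 60 * df)
  n <- 20000L
  h <- (far - q) / n
  g <- q + h * (0:n)
  dens <- g^(df / 2 - 1) * exp(-g / 2) / (2^(df / 2) * gamma(df / 2))
  if (q == 0 && df < 2) dens[1] <- 0  # integrable singularity at 0
  w <- c(1, rep(c(4, 2), length.out = n - 1), 1)
  sum(w * dens) * h / 3
}

# Binomial log-pmf by explicit factorial arithmetic on log scale via
# cumulative sums of logs (no lchoose/dbinom).
oracle_log_binom <- function(k, n, p) {
  log_fact <- function(m) if (m == 0) 0 else sum(log(seq_len(m)))
  log_fact(n) - log_fact(k) - log_fact(n - k) +
    k * log(p) + (n - k) * log(1 - p)
}

# Fixed 4-cell toy table: two orientations x two references, 10 trials each.
toy_trials <- function() {
  grid <- expand.grid(reference = c("primary", "mirrored"),
                      orientation_deg = c(-1, 1),
                      stringsAsFactors = FALSE)
  k <- c(2, 3, 8, 6)  # successes per cell, fixed
  rows <- lapply(seq_len(4), function(i) {
    tibble::tibble(
      participant = "t01", task = "symmetric",
      orientation_band = "horizontal",
      reference = grid$reference[i],
      orientation_deg = grid$orientation_deg[i],
      response = rep(c(1, 0), c(k[i], 10 - k[i]))
    )
  })
  dplyr::bind_rows(rows)
}

# Trial table with exactly flat responses (p = 0.5, independent of theta).
flat_trials <- function(seed = 404, participant = "flat") {
  grid <- expand.grid(reference = c("primary", "mirrored"),
                      orientation_deg = seq(-2, 2, 0.5),
                      stringsAsFactors = FALSE)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  resp <- withr_seed(stats::rbinom(nrow(grid) * 30, 1, 0.5))
  tibble::tibble(
    participant = participant, task = "symmetric",
    orientation_band = "horizontal",
    reference = rep(grid$reference, each = 30),
    orientation_deg = rep(grid$orientation_deg, each = 30),
    response = resp
  )
}

random_symmetric_params <- function() {
  l <- stats::runif(4, 0, 0.2)
  symmetric_params(
    delta_s = stats::runif(1, -3, 3), delta_d = stats::runif(1, -2, 2),
    sigma_primary = stats::runif(1, 0.1, 3),
    sigma_mirrored = stats::runif(1, 0.1, 3),
    lam1 = l[1], lam2 = l[2], lam1p = l[3], lam2p = l[4],
    lam_star = stats::runif(1, 0, 0.1)
  )
}
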