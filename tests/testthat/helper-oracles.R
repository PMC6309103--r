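# Independent oracles used to validate the package's estimators and Bayes
# factors. These deliberately avoid the package's code paths: plain
# normal-equation sums, fixed-grid quadrature, and an Euler-integral
# hypergeometric function.

# OLS of y on x by explicit normal equations; rmsr uses denominator n.
ols_bruteforce <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  list(intercept = a, slope = b, rmsr = sqrt(rss / n))
}

# JZS one-sample BF10 by trapezoid quadrature on a fixed log-g grid.
jzs_bf_gridquad <- function(t_stat, n, r_scale = sqrt(2) / 2,
                            m_grid = 40001L) {
  nu <- n - 1
  z <- seq(-30, 30, length.out = m_grid)
  g <- exp(z)
  log_f <- -0.5 * log(1 + n * g) -
    ((nu + 1) / 2) * log(1 + t_stat^2 / ((1 + n * g) * nu)) +
    0.5 * log(r_scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
    r_scale^2 / (2 * g) +
    z  # Jacobian dg = g dz
  m <- max(log_f)
  h <- z[2] - z[1]
  w <- rep(h, m_grid); w[c(1, m_grid)] <- h / 2
  log_num <- m + log(sum(exp(log_f - m) * w))
  log_den <- -((nu + 1) / 2) * log(1 + t_stat^2 / nu)
  exp(log_num - log_den)
}

# 2F1(1/2, 1/2; c; z) via the Euler integral representation
#   2F1(a, b; c; z) = 1/B(b, c-b) * int_0^1 t^(b-1)(1-t)^(c-b-1)(1-zt)^(-a) dt
# with a = b = 1/2; the substitution t = s^2 removes the endpoint
# singularity and Simpson's rule does the rest. z may be a vector in [0,1).
hyp2f1_euler <- function(c_par, z) {
  m <- 401L
  s <- seq(0, 1, length.out = m)
  w <- c(1, rep(c(4, 2), length.out = m - 2), 1)
  w <- w * (s[2] - s[1]) / 3
  t2 <- s^2
  base <- outer(t2, z, function(t, zz) (1 - zz * t)^(-0.5))
  tw <- 2 * (1 - t2)^(c_par - 1.5)  # t^(-1/2) dt = 2 ds
  colSums(base * tw * w) / beta(0.5, c_par - 0.5)
}

# Bayesian correlation oracle: posterior over rho on a fixed fine grid with
# the Euler-integral 2F1; returns BF10 and posterior summaries.
corr_bf_oracle <- function(r_obs, n, kappa = 1, m_grid = 8001L) {
  rho <- seq(-0.99995, 0.99995, length.out = m_grid)
  ll <- ((n - 1) / 2) * log(1 - rho^2) -
    (n - 1.5) * log(1 - rho * r_obs) +
    log(hyp2f1_euler(n - 0.5, (1 + rho * r_obs) / 2))
  ll0 <- log(hyp2f1_euler(n - 0.5, 0.5))
  lp <- (1 / kappa - 1) * log(1 - rho^2)
  h <- rho[2] - rho[1]
  tw <- rep(h, m_grid); tw[c(1, m_grid)] <- h / 2
  m <- max(ll + lp)
  num <- sum(exp(ll + lp - m) * tw)
  den_prior <- sum(exp(lp) * tw)
  bf10 <- exp(m + log(num) - log(den_prior) - ll0)
  post <- exp(ll + lp - m); post <- post / sum(post * tw)
  cdf <- cumsum(post * tw)
  qtl <- function(p) rho[which(cdf >= p)[1]]
  med <- qtl(0.5)
  dev <- abs(rho - med); ord <- order(dev)
  cw <- cumsum(post[ord] * tw[ord])
  mad_post <- dev[ord][which(cw >= 0.5)[1]]
  list(bf10 = bf10, median = med, mad = mad_post,
       ci90 = c(qtl(0.05), qtl(0.95)))
}

# Construct a length-n vector pair with an exact sample correlation r.
make_pair_with_r <- function(n, r, seed = 1) {
  withr::with_seed(seed, {
    x <- as.numeric(scale(seq_len(n)))
    e <- rnorm(n)
    e <- as.numeric(scale(residuals(stats::lm(e ~ x))))
    list(x = x, y = r * x + sqrt(1 - r^2) * e)
  })
}

# Construct a vector with an exact one-sample t statistic against 0.
make_x_with_t <- function(n, t_stat, seed = 1) {
  withr::with_seed(seed, {
    z <- as.numeric(scale(rnorm(n)))  # mean 0, sd 1 exactly
    z + t_stat / sqrt(n)
  })
}

# Run the full measurement path for one simulated cohort and return the
# per-participant ground truth joined with both task's estimates.
cohort_summary <- function(n = 63, seed = 1,
                           hyperparams = cohort_hyperparams()) {
  withr::local_seed(seed)
  parts <- sample_participants(n, hyperparams, seed = NULL)
  sim <- simulate_cohort(parts, seed = NULL)
  measures <- production_measures(remove_startup(sim$production))
  centered <- center_durations(filter_outliers(sim$reproduction)$trials)
  fits <- central_tendency_fits(centered)
  out <- dplyr::inner_join(measures, fits, by = "participant_id")
  dplyr::inner_join(
    out, dplyr::select(parts, "participant_id", "clock_cv"),
    by = "participant_id")
}

# Model-comparison input for a simulated cohort: centered kept trials with
# the scaled RMSR as the participant-level measure.
cohort_model_data <- function(n = 63, seed = 1,
                              hyperparams = cohort_hyperparams()) {
  withr::local_seed(seed)
  parts <- sample_participants(n, hyperparams, seed = NULL)
  sim <- simulate_cohort(parts, seed = NULL)
  measures <- production_measures(remove_startup(sim$production))
  centered <- center_durations(filter_outliers(sim$reproduction)$trials)
  dplyr::inner_join(
    centered,
    dplyr::select(measures, "participant_id", measure = "scaled_rmsr"),
    by = "participant_id")
}
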