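#' Interpret a Bayes factor on Jeffreys-style evidence bands
#'
#' Maps `bf10` to the conventional ordinal evidence categories (anecdotal,
#' moderate, strong, very strong, extreme), symmetric about 1: Bayes factors
#' below 1 are inverted and reported as evidence for the null, so every
#' label describes evidence progressively greater than 1. A Bayes factor of
#' exactly 1 is inconclusive.
#'
#' @param bf10 Positive Bayes factor for the alternative over the null.
#' @return A character label such as `"anecdotal evidence for H0"` or
#'   `"extreme evidence for H1"`.
#' @examples
#' interpret_bf(1)
#' interpret_bf(325.58)
#' @export
interpret_bf <- function(bf10) {
  if (length(bf10) != 1L || !is.finite(bf10) || bf10 <= 0) {
    stop("bf10 must be a single positive finite number", call. = FALSE)
  }
  if (bf10 == 1) return("inconclusive")
  direction <- if (bf10 > 1) "H1" else "H0"
  b <- max(bf10, 1 / bf10)
  band <- if (b <= 3) "anecdotal"
  else if (b <= 10) "moderate"
  else if (b <= 30) "strong"
  else if (b <= 100) "very strong"
  else "extreme"
  paste0(band, " evidence for ", direction)
}

new_bf_result <- function(log_bf10, numerical_error, method, extra = list()) {
  out <- c(list(
    bf10 = exp(log_bf10),
    log_bf10 = log_bf10,
    numerical_error = numerical_error,
    interpretation = interpret_bf(exp(log_bf10)),
    method = method
  ), extra)
  class(out) <- "bf_result"
  out
}

#' @export
print.bf_result <- function(x, ...) {
  cat("<bf_result> ", x$method, "\n", sep = "")
  cat(sprintf("  BF10 = %.6g (log BF10 = %.4f, numerical error ~ %.2g)\n",
              x$bf10, x$log_bf10, x$numerical_error))
  cat("  ", x$interpretation, "\n", sep = "")
  if (!is.null(x$posterior_median_r)) {
    cat(sprintf("  posterior median r = %.3f, MAD = %.3f, %d%% CI (%.3f, %.3f)\n",
                x$posterior_median_r, x$posterior_mad,
                round(100 * x$ci_level),
                x$credible_interval[1], x$credible_interval[2]))
  }
  invisible(x)
}

# log density of InverseGamma(shape, scale) at x
log_dinvgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Default-prior (JZS) one-sample Bayesian t test
#'
#' Bayes factor for a nonzero mean against the point null `null_value`,
#' using the Jeffreys--Zellner--Siow default prior: a Cauchy prior with
#' scale `prior_scale` on the standardized effect size, equivalently a
#' normal prior on the effect with variance `g`, `g ~
#' InverseGamma(1/2, prior_scale^2/2)`, integrated out by one-dimensional
#' numerical quadrature. The result depends on the data only through the t
#' statistic and n, and is therefore invariant under affine rescaling of
#' the data about the null value.
#'
#' @param x Numeric vector, at least 2 finite values with nonzero variance.
#' @param null_value Null mean (default 0).
#' @param prior_scale Cauchy prior scale on effect size (default
#'   `sqrt(2)/2`, the conventional "medium" width).
#' @return A `bf_result` with `bf10`, `log_bf10`, `numerical_error`
#'   (relative quadrature error), an interpretation label, and the
#'   underlying `t` and `n`.
#' @examples
#' bf_one_sample(c(0.8, 1.1, 1.2, 0.9, 1.3), null_value = 0)
#' @export
bf_one_sample <- function(x, null_value = 0, prior_scale = sqrt(2) / 2) {
  x <- as.numeric(x)
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("x must contain at least 2 finite values", call. = FALSE)
  }
  if (prior_scale <= 0) stop("prior_scale must be positive", call. = FALSE)
  n <- length(x)
  s <- sd(x)
  if (s == 0) {
    stop("degenerate data: x has zero variance", call. = FALSE)
  }
  t_stat <- (mean(x) - null_value) / (s / sqrt(n))
  log_bf10 <- jzs_log_bf(t_stat, n, prior_scale)
  new_bf_result(log_bf10$value, log_bf10$rel_error,
                method = "JZS one-sample t test",
                extra = list(t = t_stat, n = n, prior_scale = prior_scale))
}

# log BF10 for the JZS one-sample test, by quadrature over g on (0, Inf)
# mapped to u in (0,1) via g = u/(1-u).
jzs_log_bf <- function(t_stat, n, prior_scale) {
  nu <- n - 1
  log_h1_integrand <- function(g) {
    -0.5 * log1p(n * g) -
      ((nu + 1) / 2) * log1p(t_stat^2 / ((1 + n * g) * nu)) +
      log_dinvgamma(g, 0.5, prior_scale^2 / 2)
  }
  log_h0 <- -((nu + 1) / 2) * log1p(t_stat^2 / nu)
  # locate the integrand's scale for stable exponentiation
  probe_u <- seq(1e-6, 1 - 1e-6, length.out = 101)
  probe_g <- probe_u / (1 - probe_u)
  m <- max(log_h1_integrand(probe_g) - 2 * log(1 - probe_u))
  f <- function(u) {
    g <- u / (1 - u)
    exp(log_h1_integrand(g) - 2 * log(1 - u) - m)
  }
  q <- integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 0,
                 subdivisions = 400L)
  list(value = m + log(q$value) - log_h0,
       rel_error = q$abs.error / q$value)
}
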