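#' Specify a fixed-effects structure for model comparison
#'
#' Describes one candidate linear mixed model for the centered reproduction
#' data. Every model contains an intercept and a participant random
#' intercept; fixed terms are drawn from `"presented_duration"` (the
#' central-tendency slope), `"order"` (task-order condition), `"measure"`
#' (a per-participant clock-variability measure such as the scaled RMSR),
#' and `"measure:presented_duration"` (modulation of the central-tendency
#' slope by the measure; requires both main effects).
#'
#' @param name Model label.
#' @param fixed_terms Character vector of fixed terms (may be empty for the
#'   intercept-only baseline; `"intercept"` is implied and may be listed).
#' @return A list of class `model_spec`.
#' @examples
#' model_spec("duration + measure",
#'            c("presented_duration", "measure", "measure:presented_duration"))
#' @export
model_spec <- function(name, fixed_terms = character()) {
  allowed <- c("intercept", "presented_duration", "order", "measure",
               "measure:presented_duration")
  fixed_terms <- unique(as.character(fixed_terms))
  unknown <- setdiff(fixed_terms, allowed)
  if (length(unknown)) {
    stop("unknown fixed term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fixed_terms <- union("intercept", fixed_terms)
  if ("measure:presented_duration" %in% fixed_terms &&
      !all(c("measure", "presented_duration") %in% fixed_terms)) {
    stop("the measure x presented_duration interaction requires both main ",
         "effects", call. = FALSE)
  }
  structure(list(name = as.character(name),
                 fixed_terms = fixed_terms,
                 random_terms = "participant_intercept"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, ": ~ ",
      paste(setdiff(x$fixed_terms, "intercept"), collapse = " + "),
      if (length(x$fixed_terms) == 1L) "1",
      " + (1 | participant)\n", sep = "")
  invisible(x)
}

# design columns (centered) for the non-intercept fixed terms of a model
build_fixed_design <- function(data, terms) {
  cols <- list()
  ctr <- function(v) v - mean(v)
  pres <- ctr(data$presented_duration)
  meas <- if ("measure" %in% names(data)) ctr(data$measure) else NULL
  for (tm in setdiff(terms, "intercept")) {
    cols[[tm]] <- switch(
      tm,
      "presented_duration" = pres,
      "order" = ctr(ifelse(data$order_condition == "production_first",
                           -0.5, 0.5)),
      "measure" = meas,
      "measure:presented_duration" = ctr(meas * pres)
    )
    if (is.null(cols[[tm]])) {
      stop("data lacks the 'measure' column required by term '", tm, "'",
           call. = FALSE)
    }
  }
  if (!length(cols)) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate design: fixed-effect columns are collinear",
         call. = FALSE)
  }
  X
}

# sufficient statistics for the marginal likelihood of
# y = mu + X beta + Z b + e with flat prior on mu and Jeffreys prior on
# sigma^2. Z is the participant indicator matrix, so Z'Z is diagonal and
# only small crossproducts are kept; solves use the Schur complement of the
# diagonal participant block.
model_suffstats <- function(y, X, participant) {
  f <- factor(participant)
  nj <- as.numeric(table(f))
  p <- ncol(X)
  list(
    n = length(y), p = p, J = nlevels(f), nj = nj,
    XtX = if (p) crossprod(X) else NULL,
    XtZ = if (p) t(rowsum(X, f)) else NULL,
    Xty = if (p) drop(crossprod(X, y)) else numeric(0),
    Xt1 = if (p) colSums(X) else numeric(0),
    Zty = drop(rowsum(y, f)),
    yty = sum(y^2), sum_y = sum(y),
    logdet_XtX = if (p) determinant(crossprod(X))$modulus[1] else 0
  )
}

# log p(y | g, h) up to no constants: V = I + g n X (X'X)^-1 X' + h Z Z',
# mu and sigma^2 integrated out analytically.
log_ml_gh <- function(st, g, h) {
  cj <- st$nj + 1 / h
  if (st$p) {
    # A = [[X'X (1 + 1/(g n)), X'Z], [Z'X, diag(cj)]]
    A11 <- st$XtX * (1 + 1 / (g * st$n))
    B <- st$XtZ %*% (t(st$XtZ) / cj)          # A12 A22^-1 A21
    S <- A11 - B
    Rs <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(Rs)) return(-Inf)
    logdet_A <- sum(log(cj)) + 2 * sum(log(diag(Rs)))
    quad <- function(b1, d1, b2, d2) {
      # b' A^-1 d for b = (b1, b2), d = (d1, d2)
      ub <- b1 - drop(st$XtZ %*% (b2 / cj))
      ud <- d1 - drop(st$XtZ %*% (d2 / cj))
      sum(b2 * d2 / cj) +
        sum(backsolve(Rs, ub, transpose = TRUE) *
              backsolve(Rs, ud, transpose = TRUE))
    }
    one_A_one <- quad(st$Xt1, st$Xt1, st$nj, st$nj)
    one_A_y <- quad(st$Xt1, st$Xty, st$nj, st$Zty)
    y_A_y <- quad(st$Xty, st$Xty, st$Zty, st$Zty)
    logdet_D <- st$p * log(g * st$n) - st$logdet_XtX + st$J * log(h)
  } else {
    logdet_A <- sum(log(cj))
    one_A_one <- sum(st$nj^2 / cj)
    one_A_y <- sum(st$nj * st$Zty / cj)
    y_A_y <- sum(st$Zty^2 / cj)
    logdet_D <- st$J * log(h)
  }
  one_V_one <- st$n - one_A_one
  y_V_y <- st$yty - y_A_y
  one_V_y <- st$sum_y - one_A_y
  yRy <- y_V_y - one_V_y^2 / one_V_one
  if (yRy <= 0 || one_V_one <= 0) return(-Inf)
  lgamma((st$n - 1) / 2) - ((st$n - 1) / 2) * log(pi) -
    0.5 * (logdet_A + logdet_D) - 0.5 * log(one_V_one) -
    ((st$n - 1) / 2) * log(yRy)
}

# Laplace approximation (over log h) of
#   integral over h of p(y | g, h) InvGamma(h; 1/2, r_h^2/2) dh
laplace_over_h <- function(st, g, scale_random) {
  q <- function(v) {
    h <- exp(v)
    log_ml_gh(st, g, h) + log_dinvgamma(h, 0.5, scale_random^2 / 2) + v
  }
  opt <- optimize(q, interval = c(-14, 8), maximum = TRUE, tol = 1e-5)
  v_hat <- opt$maximum
  delta <- 1e-3
  curv <- (q(v_hat + delta) - 2 * opt$objective + q(v_hat - delta)) / delta^2
  if (!is.finite(curv) || curv >= -1e-8) {
    delta <- 0.1
    curv <- (q(v_hat + delta) - 2 * opt$objective + q(v_hat - delta)) / delta^2
    curv <- min(curv, -1e-8)
  }
  opt$objective + 0.5 * (log(2 * pi) - log(-curv))
}

# log marginal likelihood of one model: quadrature over the Zellner-Siow g
# (fixed effects), Laplace over the random-intercept variance ratio h.
log_marginal_model <- function(st, scale_fixed, scale_random) {
  if (st$p == 0L) {
    return(list(log_ml = laplace_over_h(st, NULL, scale_random),
                rel_error = 0))
  }
  lf <- function(u) {
    g <- u / (1 - u)
    laplace_over_h(st, g, scale_random) +
      log_dinvgamma(g, 0.5, scale_fixed^2 / 2) - 2 * log(1 - u)
  }
  probe <- seq(0.001, 0.999, length.out = 15)
  lp <- vapply(probe, lf, numeric(1))
  m <- max(lp[is.finite(lp)])
  f <- function(u) {
    vapply(u, function(ui) exp(lf(ui) - m), numeric(1))
  }
  q <- integrate(f, 0, 1, rel.tol = 1e-5, abs.tol = 0,
                 subdivisions = 100L, stop.on.error = FALSE)
  list(log_ml = m + log(q$value), rel_error = q$abs.error / q$value)
}

#' Compare nested mixed models by default-prior Bayes factors
#'
#' Computes, for each candidate model, the marginal likelihood of the
#' centered reproduction data under a Zellner--Siow default prior on
#' standardized fixed effects (a common scale factor `g` with an
#' InverseGamma(1/2, scale^2/2) mixing density, i.e. a multivariate Cauchy
#' on effect sizes) and a participant random intercept whose variance ratio
#' is integrated out. The grand mean carries a flat prior and the residual
#' variance a Jeffreys prior, both integrated analytically; `g` is handled
#' by one-dimensional adaptive quadrature and the random-intercept variance
#' by a Laplace approximation on the log scale. Pairwise Bayes factors are
#' ratios of marginal likelihoods, so transitivity holds exactly.
#'
#' A faster cross-check backend (`backend = "bic"`) instead fits each model
#' by maximum likelihood with `lme4::lmer()` and uses the Schwarz
#' approximation `log ml ~ -BIC/2`.
#'
#' @param data Tibble of centered reproduction trials joined with a
#'   per-participant measure: columns `participant_id`,
#'   `presented_duration`, `reproduced_duration` (both centered),
#'   `order_condition`, and (if any model uses it) `measure`.
#' @param models List of [model_spec()]s; every model must nest within the
#'   largest (term-richest) model.
#' @param prior_scale_fixed Scale of the g prior on fixed effects (default
#'   `sqrt(2)/4`, the conventional "medium" width for covariates).
#' @param prior_scale_random Scale of the prior on the random-intercept
#'   variance ratio (default 1, the conventional nuisance width).
#' @param backend `"quadrature"` (default) or `"bic"`.
#' @return A list of class `bf_model_comparison`: `models`, a tibble with
#'   per-model `name`, `log_ml`, `bf_vs_first` (Bayes factor against the
#'   first model listed), `numerical_error` and `label`; and `pairwise_bf`,
#'   the matrix of Bayes factors `BF[i, j]` for model i over model j.
#' @export
bf_model_comparison <- function(data, models,
                                prior_scale_fixed = sqrt(2) / 4,
                                prior_scale_random = 1,
                                backend = c("quadrature", "bic")) {
  backend <- match.arg(backend)
  if (inherits(models, "model_spec")) models <- list(models)
  if (!length(models) || !all(vapply(models, inherits, logical(1),
                                     "model_spec"))) {
    stop("models must be a list of model_spec objects", call. = FALSE)
  }
  req <- c("participant_id", "presented_duration", "reproduced_duration",
           "order_condition")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sizes <- vapply(models, function(m) length(m$fixed_terms), integer(1))
  largest <- models[[which.max(sizes)]]
  for (m in models) {
    if (!all(m$fixed_terms %in% largest$fixed_terms)) {
      stop("model '", m$name, "' does not nest within the largest model '",
           largest$name, "'", call. = FALSE)
    }
  }
  y <- data$reproduced_duration
  if (backend == "quadrature") {
    res <- lapply(models, function(m) {
      X <- build_fixed_design(data, m$fixed_terms)
      st <- model_suffstats(y, X, data$participant_id)
      log_marginal_model(st, prior_scale_fixed, prior_scale_random)
    })
    log_ml <- vapply(res, `[[`, numeric(1), "log_ml")
    rel_err <- vapply(res, `[[`, numeric(1), "rel_error")
  } else {
    log_ml <- vapply(models, function(m) {
      terms <- setdiff(m$fixed_terms, "intercept")
      rhs <- c(vapply(terms, function(tm) switch(
        tm,
        "presented_duration" = "presented_duration",
        "order" = "order_condition",
        "measure" = "measure",
        "measure:presented_duration" = "measure:presented_duration"
      ), character(1)), "(1 | participant_id)")
      fml <- as.formula(paste("reproduced_duration ~",
                              paste(rhs, collapse = " + ")))
      fit <- lme4::lmer(fml, data = data, REML = FALSE)
      -BIC(fit) / 2
    }, numeric(1))
    rel_err <- rep(NA_real_, length(models))
  }
  names_vec <- vapply(models, `[[`, character(1), "name")
  pairwise <- outer(log_ml, log_ml, `-`)
  dimnames(pairwise) <- list(names_vec, names_vec)
  tbl <- tibble::tibble(
    name = names_vec,
    n_fixed_terms = sizes,
    log_ml = log_ml,
    bf_vs_first = exp(log_ml - log_ml[1]),
    numerical_error = rel_err,
    label = vapply(exp(pmin(pmax(log_ml - log_ml[1], -700), 700)),
                   interpret_bf, character(1))
  )
  structure(list(models = tbl, pairwise_bf = exp(pairwise),
                 log_pairwise_bf = pairwise, backend = backend),
            class = "bf_model_comparison")
}

#' @export
print.bf_model_comparison <- function(x, ...) {
  cat("<bf_model_comparison> backend: ", x$backend, "\n", sep = "")
  df <- as.data.frame(x$models)
  df$log_ml <- sprintf("%.2f", df$log_ml)
  df$bf_vs_first <- sprintf("%.4g", df$bf_vs_first)
  print(df, row.names = FALSE)
  invisible(x)
}
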