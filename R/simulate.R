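#' Simulate a 1-s production session
#'
#' Generates one participant's sequence of repeated 1-s productions. The
#' first `n_startup` trials are "start-up" trials with inflated mean
#' (`startup_mean_factor`) and inflated noise (`startup_cv_factor`); from the
#' first analyzed trial onward the mean production follows a slow linear
#' drift, `mu_one_second + drift_slope * (t - n_startup)` for session trial
#' `t > n_startup`. Each production is drawn from a normal law whose standard
#' deviation is proportional to its mean (scalar property,
#' `clock_cv * mean`), floored at 0.05 s (minimum keypress latency).
#'
#' @param params A one-row [participant_params()] table.
#' @param n_trials Total trials in the session (default 20).
#' @param n_startup Number of start-up trials at the beginning (default 2).
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return A tibble with columns `participant_id`, `order_condition`,
#'   `trial_index` (1-based session order), `produced_duration` (seconds).
#' @examples
#' p <- participant_params("P001", clock_cv = 0.1)
#' simulate_production(p, seed = 1)
#' @export
simulate_production <- function(params, n_trials = 20L, n_startup = 2L,
                                seed = NULL) {
  params <- as_participant_params(params)
  n_trials <- as.integer(n_trials)
  n_startup <- as.integer(n_startup)
  if (n_startup < 0L || n_trials < n_startup) {
    stop("need n_trials >= n_startup >= 0", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  t_idx <- seq_len(n_trials)
  startup <- t_idx <= n_startup
  mu_t <- ifelse(startup,
                 params$mu_one_second * params$startup_mean_factor,
                 params$mu_one_second +
                   params$drift_slope * (t_idx - n_startup))
  if (any(mu_t <= 0)) {
    bad <- t_idx[mu_t <= 0][1]
    stop("drift implies a non-positive mean production at trial ", bad,
         " for participant ", params$participant_id, call. = FALSE)
  }
  sd_t <- params$clock_cv * mu_t * ifelse(startup, params$startup_cv_factor, 1)
  produced <- pmax(rnorm(n_trials, mean = mu_t, sd = sd_t), .duration_floor)
  tibble::tibble(
    participant_id = params$participant_id,
    order_condition = params$order_condition,
    trial_index = t_idx,
    produced_duration = produced
  )
}

# lambda(d): weight of the sensory likelihood in the posterior-mean estimate
observer_lambda <- function(clock_cv, prior_sd, d) {
  prior_sd^2 / (prior_sd^2 + (clock_cv * d)^2)
}

#' Simulate a multi-duration reproduction session
#'
#' Generates one participant's reproduction trials under a Bayesian-observer
#' model. On a trial with presented duration `d` the percept is
#' `x ~ N(d, clock_cv * d)`; the observer's estimate is the posterior mean
#' under a static Gaussian prior,
#' `e = lambda(d) * x + (1 - lambda(d)) * prior_mean` with
#' `lambda(d) = prior_sd^2 / (prior_sd^2 + (clock_cv * d)^2)`; the response
#' is `N(e, motor_cv * e)`. All durations are floored at 0.05 s. Within each
#' block every duration level appears equally often, in seeded random order.
#'
#' @inheritParams simulate_production
#' @param design A [task_design()].
#' @return A tibble with columns `participant_id`, `order_condition`,
#'   `block`, `trial_index` (1-based within block), `presented_duration`,
#'   `reproduced_duration` (seconds).
#' @examples
#' p <- participant_params("P001", clock_cv = 0.15)
#' head(simulate_reproduction(p, seed = 1))
#' @export
simulate_reproduction <- function(params, design = task_design(),
                                  seed = NULL) {
  params <- as_participant_params(params)
  if (!inherits(design, "task_design")) {
    stop("design must be a task_design()", call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  per_block <- design$presentations_per_level_per_block
  presented <- unlist(lapply(seq_len(design$n_blocks), function(b) {
    sample(rep(design$duration_levels, each = per_block))
  }))
  n <- length(presented)
  percept <- rnorm(n, mean = presented, sd = params$clock_cv * presented)
  lam <- observer_lambda(params$clock_cv, params$prior_sd, presented)
  estimate <- pmax(lam * percept + (1 - lam) * params$prior_mean,
                   .duration_floor)
  reproduced <- pmax(rnorm(n, mean = estimate, sd = params$motor_cv * estimate),
                     .duration_floor)
  tibble::tibble(
    participant_id = params$participant_id,
    order_condition = params$order_condition,
    block = rep(seq_len(design$n_blocks), each = design$trials_per_block),
    trial_index = rep(seq_len(design$trials_per_block), design$n_blocks),
    presented_duration = presented,
    reproduced_duration = reproduced
  )
}

#' Analytic expected central-tendency slope of the observer model
#'
#' Returns the expected ordinary-least-squares slope of reproduced on
#' presented duration under the Bayesian-observer model of
#' [simulate_reproduction()], for a balanced design over `duration_levels`.
#' With `lambda(d)` the likelihood weight, the expected response at level
#' `d` is `lambda(d) * d + (1 - lambda(d)) * prior_mean` (motor noise is
#' mean-preserving), so the expected slope is
#' `sum((d - dbar) * (lambda * d + (1 - lambda) * prior_mean)) /
#'  sum((d - dbar)^2)`.
#' The slope is 1 for a noise-free clock (full reliance on the likelihood),
#' tends to 0 as clock noise grows (full reliance on the prior), and is
#' strictly decreasing in `clock_cv`.
#'
#' @param params A one-row [participant_params()] table.
#' @param duration_levels At least two distinct presented durations.
#' @return The expected OLS slope (dimensionless).
#' @examples
#' p <- participant_params("P001", clock_cv = 0.15)
#' expected_central_slope(p)
#' @export
expected_central_slope <- function(params,
                                   duration_levels = c(1.17, 1.4, 1.68)) {
  params <- as_participant_params(params)
  d <- as.numeric(duration_levels)
  if (length(unique(d)) < 2L) {
    stop("need at least 2 distinct duration levels", call. = FALSE)
  }
  lam <- observer_lambda(params$clock_cv, params$prior_sd, d)
  ey <- lam * d + (1 - lam) * params$prior_mean
  dbar <- mean(d)
  sum((d - dbar) * ey) / sum((d - dbar)^2)
}

#' Monte-Carlo central-tendency slopes for one parameter set
#'
#' Simulates many independent reproduction sessions under the observer model
#' and returns each session's OLS slope of reproduced on presented duration.
#' Used as a simulation oracle against [expected_central_slope()] and for
#' power-style checks. The draw logic is identical to
#' [simulate_reproduction()] but vectorized across sessions (trial order
#' within a block does not affect the slope).
#'
#' @inheritParams simulate_reproduction
#' @param n_sessions Number of independent sessions.
#' @return Numeric vector of `n_sessions` OLS slopes.
#' @examples
#' p <- participant_params("P001", clock_cv = 0.15)
#' mean(mc_central_slope(p, n_sessions = 100, seed = 1))
#' @export
mc_central_slope <- function(params, design = task_design(),
                             n_sessions = 1000L, seed = NULL) {
  params <- as_participant_params(params)
  if (!is.null(seed)) withr::local_seed(seed)
  d <- rep(design$duration_levels,
           each = design$presentations_per_level_per_block * design$n_blocks)
  n <- length(d)
  lam <- observer_lambda(params$clock_cv, params$prior_sd, d)
  dc <- d - mean(d)
  ssd <- sum(dc^2)
  slopes <- numeric(n_sessions)
  for (s in seq_len(n_sessions)) {
    x <- rnorm(n, mean = d, sd = params$clock_cv * d)
    e <- pmax(lam * x + (1 - lam) * params$prior_mean, .duration_floor)
    y <- pmax(rnorm(n, mean = e, sd = params$motor_cv * e), .duration_floor)
    slopes[s] <- sum(dc * y) / ssd
  }
  slopes
}

#' Simulate both tasks for a cohort
#'
#' Convenience wrapper running [simulate_production()] and
#' [simulate_reproduction()] for every row of a participant table under one
#' seeded RNG stream.
#'
#' @param participants Tibble of participants from [sample_participants()].
#' @param design A [task_design()].
#' @param n_trials,n_startup Production-session shape, see
#'   [simulate_production()].
#' @param seed Integer seed, or `NULL`.
#' @return A list with tibbles `production` and `reproduction`.
#' @examples
#' coh <- sample_participants(2, seed = 1)
#' str(simulate_cohort(coh, seed = 1), max.level = 1)
#' @export
simulate_cohort <- function(participants, design = task_design(),
                            n_trials = 20L, n_startup = 2L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  rows <- seq_len(nrow(participants))
  prod <- lapply(rows, function(i) {
    simulate_production(participants[i, ], n_trials = n_trials,
                        n_startup = n_startup, seed = NULL)
  })
  repr <- lapply(rows, function(i) {
    simulate_reproduction(participants[i, ], design = design, seed = NULL)
  })
  list(production = dplyr::bind_rows(prod),
       reproduction = dplyr::bind_rows(repr))
}
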