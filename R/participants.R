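#' Generative parameters for one simulated participant
#'
#' Bundles the ground-truth parameters of the Bayesian-observer model used by
#' the synthetic data generator. Timing noise obeys the scalar property: the
#' standard deviation of a timed interval is `clock_cv` times its mean, both
#' in the production task (around the internal 1-s representation) and in the
#' sensory likelihood of the reproduction task. A static Gaussian prior
#' (`prior_mean`, `prior_sd`) over durations drives the central-tendency
#' effect; scalar motor noise (`motor_cv`) is applied at response execution.
#'
#' @param participant_id Identifier (coerced to character).
#' @param clock_cv Coefficient of variation of clock noise (dimensionless,
#'   >= 0).
#' @param mu_one_second Internal representation of 1 s, in seconds (> 0).
#' @param drift_slope Slow linear change of the internal 1-s representation,
#'   in seconds per trial.
#' @param startup_mean_factor Mean inflation of start-up production trials
#'   (>= 1).
#' @param startup_cv_factor Noise inflation of start-up production trials
#'   (>= 1).
#' @param motor_cv Coefficient of variation of motor noise (>= 0).
#' @param prior_mean Mean of the observer's duration prior, seconds (> 0).
#'   Defaults to the mean of the standard design durations
#'   (1.17, 1.4, 1.68 s).
#' @param prior_sd Standard deviation of the duration prior, seconds (> 0).
#' @param order_condition `"production_first"` or `"reproduction_first"`.
#'
#' @return A one-row tibble of class `participant_params`.
#' @examples
#' participant_params("P001", clock_cv = 0.1)
#' @export
participant_params <- function(participant_id,
                               clock_cv = 0.12,
                               mu_one_second = 1,
                               drift_slope = 0,
                               startup_mean_factor = 1.8,
                               startup_cv_factor = 2.5,
                               motor_cv = 0.05,
                               prior_mean = NULL,
                               prior_sd = 0.25,
                               order_condition = c("production_first",
                                                   "reproduction_first")) {
  order_condition <- match.arg(order_condition)
  if (is.null(prior_mean)) prior_mean <- mean(.default_levels)
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    clock_cv = as.numeric(clock_cv),
    mu_one_second = as.numeric(mu_one_second),
    drift_slope = as.numeric(drift_slope),
    startup_mean_factor = as.numeric(startup_mean_factor),
    startup_cv_factor = as.numeric(startup_cv_factor),
    motor_cv = as.numeric(motor_cv),
    prior_mean = as.numeric(prior_mean),
    prior_sd = as.numeric(prior_sd),
    order_condition = order_condition
  )
  validate_participant_params(out)
  class(out) <- c("participant_params", class(out))
  out
}

validate_participant_params <- function(p) {
  num <- c("clock_cv", "mu_one_second", "drift_slope", "startup_mean_factor",
           "startup_cv_factor", "motor_cv", "prior_mean", "prior_sd")
  for (f in num) {
    v <- p[[f]]
    if (any(!is.finite(v))) {
      stop("participant parameter '", f, "' must be finite", call. = FALSE)
    }
  }
  chk <- function(cond, msg) if (any(!cond)) stop(msg, call. = FALSE)
  chk(p$clock_cv >= 0, "clock_cv must be >= 0")
  chk(p$motor_cv >= 0, "motor_cv must be >= 0")
  chk(p$mu_one_second > 0, "mu_one_second must be > 0")
  chk(p$prior_mean > 0, "prior_mean must be > 0")
  chk(p$prior_sd > 0, "prior_sd must be > 0")
  chk(p$startup_mean_factor >= 1, "startup_mean_factor must be >= 1")
  chk(p$startup_cv_factor >= 1, "startup_cv_factor must be >= 1")
  chk(p$order_condition %in% c("production_first", "reproduction_first"),
      "order_condition must be 'production_first' or 'reproduction_first'")
  invisible(p)
}

as_participant_params <- function(params) {
  if (is.data.frame(params)) {
    if (nrow(params) != 1L) {
      stop("expected parameters for exactly one participant, got ",
           nrow(params), " rows", call. = FALSE)
    }
    validate_participant_params(params)
    return(params)
  }
  stop("params must be a one-row participant_params table", call. = FALSE)
}

#' Cohort-level hyperparameters for the participant sampler
#'
#' Each field of [participant_params()] is given a sampling rule used by
#' [sample_participants()]: a single number (held fixed for all
#' participants), a length-2 numeric `c(min, max)` (uniform), or a list such
#' as `list(dist = "normal", mean = 0, sd = 1)` /
#' `list(dist = "lognormal", meanlog = 0, sdlog = 0.2)` /
#' `list(dist = "uniform", min = 0, max = 1)`.
#'
#' Defaults describe a young-adult cohort: clock coefficients of variation
#' uniform on 0.05--0.25, internal 1-s representations lognormal around
#' 0.95 s, small per-trial drifts centered near zero (mean -0.0055 s/trial,
#' SD 0.03), start-up inflation factors 1.8 (mean) and 2.5 (noise), motor
#' noise CV 0.05, and a duration prior centered on the design mean with SD
#' 0.25 s.
#'
#' @param ... Named overrides of individual fields.
#' @return A named list of sampling rules.
#' @examples
#' cohort_hyperparams(clock_cv = c(0.1, 0.2), drift_slope = 0)
#' @export
cohort_hyperparams <- function(...) {
  defaults <- list(
    clock_cv = c(0.05, 0.25),
    mu_one_second = list(dist = "lognormal", meanlog = log(0.95), sdlog = 0.2),
    drift_slope = list(dist = "normal", mean = -0.0055, sd = 0.03),
    startup_mean_factor = 1.8,
    startup_cv_factor = 2.5,
    motor_cv = 0.05,
    prior_mean = mean(.default_levels),
    prior_sd = 0.25
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(dots)] <- dots
  defaults
}

draw_hyper <- function(rule, n, field) {
  bad <- function(msg) {
    stop("improper hyperparameter for '", field, "': ", msg, call. = FALSE)
  }
  if (is.numeric(rule) && length(rule) == 1L) {
    if (!is.finite(rule)) bad("value must be finite")
    return(rep(rule, n))
  }
  if (is.numeric(rule) && length(rule) == 2L) {
    if (any(!is.finite(rule)) || rule[1] > rule[2]) bad("need min <= max")
    return(runif(n, rule[1], rule[2]))
  }
  if (is.list(rule)) {
    dist <- rule$dist
    if (identical(dist, "uniform")) {
      if (is.null(rule$min) || is.null(rule$max) || rule$min > rule$max) {
        bad("need min <= max")
      }
      return(runif(n, rule$min, rule$max))
    }
    if (identical(dist, "normal")) {
      if (is.null(rule$sd) || rule$sd < 0) bad("need sd >= 0")
      return(rnorm(n, rule$mean, rule$sd))
    }
    if (identical(dist, "lognormal")) {
      if (is.null(rule$sdlog) || rule$sdlog < 0) bad("need sdlog >= 0")
      return(rlnorm(n, rule$meanlog, rule$sdlog))
    }
    bad(paste0("unknown distribution '", dist, "'"))
  }
  bad("rule must be a number, a length-2 range, or a distribution list")
}

#' Sample a cohort of simulated participants
#'
#' Draws `n` ground-truth parameter sets from cohort-level hyperparameters.
#' Task order alternates with the parity of the sequential participant
#' number: odd indices are assigned `reproduction_first`, even indices
#' `production_first` (a counterbalanced design).
#'
#' Because a participant cannot keep producing intervals once the drifting
#' mean would reach zero, draws whose internal 1-s representation and drift
#' slope jointly imply a mean production below 0.1 s within a standard
#' 18-analyzed-trial session are rejected and redrawn (strong negative
#' drifts therefore co-occur with long baseline productions, as observed
#' empirically).
#'
#' @param n Number of participants (>= 0).
#' @param hyperparams Sampling rules, see [cohort_hyperparams()].
#' @param seed Integer seed; identical seed and hyperparameters reproduce
#'   the cohort exactly. `NULL` continues the current RNG stream.
#' @return A tibble with one row per participant (the fields of
#'   [participant_params()]).
#' @examples
#' sample_participants(4, seed = 1)
#' @export
sample_participants <- function(n, hyperparams = cohort_hyperparams(),
                                seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != round(n)) {
    stop("n must be a single non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  missing_f <- setdiff(names(cohort_hyperparams()), names(hyperparams))
  if (length(missing_f)) {
    stop("hyperparams missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) withr::local_seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  fields <- names(cohort_hyperparams())
  draws <- lapply(fields, function(f) draw_hyper(hyperparams[[f]], n, f))
  names(draws) <- fields
  # redraw (mu, drift) pairs that would drive the mean production to zero
  # within a standard session of 18 analyzed trials
  for (iter in seq_len(1000L)) {
    bad <- draws$mu_one_second + 18 * draws$drift_slope <= 0.1
    if (!any(bad)) break
    draws$mu_one_second[bad] <-
      draw_hyper(hyperparams$mu_one_second, sum(bad), "mu_one_second")
    draws$drift_slope[bad] <-
      draw_hyper(hyperparams$drift_slope, sum(bad), "drift_slope")
  }
  if (any(draws$mu_one_second + 18 * draws$drift_slope <= 0.1)) {
    stop("hyperparams place almost all mass on sessions whose drift ",
         "implies non-positive productions", call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = ids,
    clock_cv = draws$clock_cv,
    mu_one_second = draws$mu_one_second,
    drift_slope = draws$drift_slope,
    startup_mean_factor = draws$startup_mean_factor,
    startup_cv_factor = draws$startup_cv_factor,
    motor_cv = draws$motor_cv,
    prior_mean = draws$prior_mean,
    prior_sd = draws$prior_sd,
    order_condition = ifelse(seq_len(n) %% 2L == 1L,
                             "reproduction_first", "production_first")
  )
  if (n > 0) validate_participant_params(out)
  out
}
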