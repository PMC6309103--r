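#' Drop start-up trials and recode trial indices
#'
#' The first trials of a production session are systematically longer and
#' more variable ("start-up trials"). This removes the first `n_startup`
#' trials of each participant (by presentation order) and renumbers the
#' remaining trials 1..k, so that a 20-trial session with two start-up
#' trials yields analyzed trials coded 1--18.
#'
#' @param trials Production tibble (`participant_id`, `trial_index`,
#'   `produced_duration`, ...).
#' @param n_startup Number of initial trials to drop per participant
#'   (default 2).
#' @return The trials tibble without start-up trials, `trial_index` recoded
#'   to start at 1 within participant.
#' @export
remove_startup <- function(trials, n_startup = 2L) {
  n_startup <- as.integer(n_startup)
  if (n_startup < 0L) stop("n_startup must be >= 0", call. = FALSE)
  counts <- dplyr::count(trials, .data$participant_id)
  short <- counts$participant_id[counts$n <= n_startup]
  if (length(short)) {
    stop("n_startup (", n_startup, ") leaves no analyzed trials for ",
         "participant(s): ", paste(short, collapse = ", "), call. = FALSE)
  }
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::slice((n_startup + 1L):dplyr::n()) |>
    dplyr::mutate(trial_index = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Screen out aberrant producers
#'
#' A participant is excluded when the number of analyzed productions
#' strictly exceeding `limit` is at least `min_count`. With the defaults
#' (3 s, 5 trials) a participant producing five or more intervals over 3 s
#' (after start-up removal) is flagged as failing to follow task
#' instructions.
#'
#' @param trials Analyzed production tibble (after [remove_startup()]).
#' @param limit Aberrance limit in seconds (default 3).
#' @param min_count Minimum number of over-limit productions for exclusion
#'   (default 5).
#' @return A list of class `screening_report`: `kept_ids`, `excluded_ids`,
#'   and `counts`, a tibble with the per-participant number of over-limit
#'   productions.
#' @export
screen_participants <- function(trials, limit = 3, min_count = 5L) {
  if (limit <= 0) stop("limit must be positive", call. = FALSE)
  if (min_count < 1L) stop("min_count must be >= 1", call. = FALSE)
  counts <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_analyzed = dplyr::n(),
      n_over_limit = sum(.data$produced_duration > limit),
      .groups = "drop"
    )
  excluded <- counts$participant_id[counts$n_over_limit >= min_count]
  structure(
    list(kept_ids = setdiff(counts$participant_id, excluded),
         excluded_ids = excluded,
         counts = counts,
         limit = limit,
         min_count = as.integer(min_count)),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report> kept ", length(x$kept_ids), ", excluded ",
      length(x$excluded_ids), " participant(s) (> ", x$limit, " s on >= ",
      x$min_count, " trials)\n", sep = "")
  if (length(x$excluded_ids)) {
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Variability measures for one participant's analyzed productions
#'
#' Computes the three production-task variability measures and the drift
#' fit for a single participant:
#' * `sd`: sample standard deviation (denominator n-1) of the analyzed
#'   productions, which overestimates clock noise when the mean drifts;
#' * `drift_slope`, `drift_intercept`: OLS of produced duration on the
#'   recoded trial index (1..n);
#' * `rmsr`: root mean squared residual around that line (denominator n),
#'   a drift-corrected variability measure;
#' * `scaled_rmsr`: `rmsr / mean_production`, a dimensionless clock-noise
#'   index that respects the scalar property of timing variance.
#'
#' @param trials Analyzed production tibble for one participant, with
#'   recoded `trial_index` and positive finite `produced_duration`; at least
#'   3 trials.
#' @param sd_denominator `"n-1"` (default) or `"n"` for the SD.
#' @param rmsr_denominator `"n"` (default, the literal mean squared
#'   residual) or `"n-2"` for a degrees-of-freedom-corrected variant.
#' @return A one-row tibble: `participant_id`, `n_analyzed`,
#'   `mean_production`, `sd`, `drift_slope`, `drift_intercept`, `rmsr`,
#'   `scaled_rmsr`.
#' @examples
#' p <- participant_params("P001", clock_cv = 0.1)
#' trials <- remove_startup(simulate_production(p, seed = 1))
#' production_summary(trials)
#' @export
production_summary <- function(trials, sd_denominator = c("n-1", "n"),
                               rmsr_denominator = c("n", "n-2")) {
  sd_denominator <- match.arg(sd_denominator)
  rmsr_denominator <- match.arg(rmsr_denominator)
  id <- unique(trials$participant_id)
  if (length(id) != 1L) {
    stop("production_summary expects trials of exactly one participant",
         call. = FALSE)
  }
  y <- trials$produced_duration[order(trials$trial_index)]
  n <- length(y)
  if (n < 3L) {
    stop("insufficient data for participant ", id, ": need >= 3 analyzed ",
         "trials, got ", n, call. = FALSE)
  }
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("produced durations must be finite and positive (participant ",
         id, ")", call. = FALSE)
  }
  t_idx <- as.numeric(seq_len(n))
  if (sd(t_idx) == 0) stop("degenerate trial index", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, t_idx), y)
  rss <- sum(fit$residuals^2)
  ss <- sum((y - mean(y))^2)
  sd_val <- sqrt(ss / if (sd_denominator == "n-1") (n - 1) else n)
  rmsr <- sqrt(rss / if (rmsr_denominator == "n") n else (n - 2))
  mean_prod <- mean(y)
  tibble::tibble(
    participant_id = id,
    n_analyzed = n,
    mean_production = mean_prod,
    sd = sd_val,
    drift_slope = unname(fit$coefficients[2]),
    drift_intercept = unname(fit$coefficients[1]),
    rmsr = rmsr,
    scaled_rmsr = rmsr / mean_prod
  )
}

#' Variability measures for a whole cohort
#'
#' Applies [production_summary()] per participant. Participants with fewer
#' than 3 analyzed trials are dropped with a warning instead of failing the
#' whole cohort.
#'
#' @inheritParams production_summary
#' @param trials Analyzed production tibble (after [remove_startup()] and
#'   screening), any number of participants.
#' @return A tibble with one row per retained participant.
#' @export
production_measures <- function(trials, sd_denominator = c("n-1", "n"),
                                rmsr_denominator = c("n", "n-2")) {
  sd_denominator <- match.arg(sd_denominator)
  rmsr_denominator <- match.arg(rmsr_denominator)
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$participant_id == id, ]
    if (nrow(sub) < 3L) {
      warning("dropping participant ", id, ": only ", nrow(sub),
              " analyzed trial(s)", call. = FALSE)
      return(NULL)
    }
    production_summary(sub, sd_denominator, rmsr_denominator)
  })
  dplyr::bind_rows(rows)
}

#' Total drift implied by a per-trial slope
#'
#' Converts an OLS drift slope (seconds per trial) into the total drift over
#' an analyzed session, in milliseconds, by multiplying the slope by the
#' number of analyzed trials: `drift_slope * n_analyzed * 1000`. With the
#' standard 18 analyzed trials, slopes of -0.08 and 0.04 s/trial correspond
#' to total drifts of -1440 and 720 ms. (The multiplier is the trial count,
#' not the number of steps between first and last analyzed trial.)
#'
#' @param drift_slope Slope(s) in seconds per trial.
#' @param n_analyzed Number of analyzed trials (default 18).
#' @return Implied total drift in milliseconds (vectorized).
#' @examples
#' implied_total_drift(c(-0.08, 0.04))
#' @export
implied_total_drift <- function(drift_slope, n_analyzed = 18L) {
  drift_slope * n_analyzed * 1000
}
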