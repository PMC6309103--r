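#' Filter outlier reproduction trials
#'
#' Removes trials whose reproduced duration is strictly below `low` or
#' strictly above `high` (boundary values are kept; set
#' `inclusive = TRUE` to also drop values equal to the bounds). Defaults
#' mark responses faster than 500 ms or slower than 2.5 s as outliers.
#'
#' @param trials Reproduction tibble with a `reproduced_duration` column.
#' @param low,high Bounds in seconds, `0 < low < high`.
#' @param inclusive Drop boundary values too (default `FALSE`).
#' @return A list: `trials` (kept rows) and `summary`, a list with
#'   `n_input`, `n_removed`, `proportion_removed`.
#' @examples
#' p <- participant_params("P001")
#' filt <- filter_outliers(simulate_reproduction(p, seed = 1))
#' filt$summary
#' @export
filter_outliers <- function(trials, low = 0.5, high = 2.5,
                            inclusive = FALSE) {
  if (!(low > 0 && low < high)) {
    stop("outlier bounds must satisfy 0 < low < high (got low = ", low,
         ", high = ", high, ")", call. = FALSE)
  }
  y <- trials$reproduced_duration
  drop <- if (inclusive) y <= low | y >= high else y < low | y > high
  n_input <- length(y)
  n_removed <- sum(drop)
  list(
    trials = trials[!drop, , drop = FALSE],
    summary = list(
      n_input = n_input,
      n_removed = n_removed,
      proportion_removed = if (n_input == 0) 0 else n_removed / n_input
    )
  )
}

#' Center presented and reproduced durations
#'
#' Subtracts a reference duration (default 1.4 s, the middle design level)
#' from both presented and reproduced durations, so that regression
#' coefficients are interpretable relative to the center of the stimulus
#' range. Pure shift: ordering and row count are unchanged.
#'
#' @param trials Reproduction tibble with `presented_duration` and
#'   `reproduced_duration`.
#' @param reference Reference duration in seconds (default 1.4).
#' @return The tibble with both duration columns shifted by `-reference`.
#' @export
center_durations <- function(trials, reference = 1.4) {
  dplyr::mutate(
    trials,
    presented_duration = .data$presented_duration - reference,
    reproduced_duration = .data$reproduced_duration - reference
  )
}

#' Central-tendency slope for one participant
#'
#' OLS regression of reproduced on presented duration for a single
#' participant. A slope of 1 means reproductions track the stimulus exactly
#' (no influence of temporal context, full reliance on the likelihood); a
#' slope of 0 means the participant reproduces the same duration regardless
#' of the stimulus (full reliance on the prior). The slope is invariant
#' under centering of the durations.
#'
#' @param trials Reproduction tibble for one participant (centered or raw),
#'   with at least 3 trials spanning at least 2 distinct presented levels.
#' @return A one-row tibble: `participant_id`, `slope`, `intercept`,
#'   `n_trials_used`.
#' @export
central_tendency_fit <- function(trials) {
  id <- unique(trials$participant_id)
  if (length(id) != 1L) {
    stop("central_tendency_fit expects trials of exactly one participant",
         call. = FALSE)
  }
  x <- trials$presented_duration
  y <- trials$reproduced_duration
  n <- length(x)
  if (n < 3L) {
    stop("insufficient data for participant ", id, ": need >= 3 trials, got ",
         n, call. = FALSE)
  }
  if (length(unique(x)) < 2L) {
    stop("insufficient variation for participant ", id,
         ": a single presented level", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  tibble::tibble(
    participant_id = id,
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    n_trials_used = n
  )
}

#' Central-tendency slopes for a whole cohort
#'
#' Applies [central_tendency_fit()] per participant. Participants left with
#' fewer than 3 usable trials or a single presented level (e.g. after
#' outlier filtering) are excluded with a warning.
#'
#' @param trials Reproduction tibble, any number of participants.
#' @return A tibble with one row per fitted participant.
#' @export
central_tendency_fits <- function(trials) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$participant_id == id, ]
    if (nrow(sub) < 3L || length(unique(sub$presented_duration)) < 2L) {
      warning("excluding participant ", id,
              " from central-tendency fits: insufficient usable trials",
              call. = FALSE)
      return(NULL)
    }
    central_tendency_fit(sub)
  })
  dplyr::bind_rows(rows)
}

#' Mean reproduced duration per condition cell
#'
#' Summarises reproduction data (uncentered scale) as one row per presented
#' duration level and task-order condition, with cell count and mean
#' reproduced duration. Central tendency appears as cell means above the
#' shortest level and below the longest.
#'
#' @param trials Reproduction tibble (uncentered).
#' @return A tibble: `presented_duration`, `order_condition`, `n`,
#'   `mean_reproduced`.
#' @export
condition_means <- function(trials) {
  if (nrow(trials) == 0L) {
    return(tibble::tibble(presented_duration = numeric(),
                          order_condition = character(),
                          n = integer(),
                          mean_reproduced = numeric()))
  }
  trials |>
    dplyr::group_by(.data$presented_duration, .data$order_condition) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_reproduced = mean(.data$reproduced_duration),
                     .groups = "drop") |>
    dplyr::arrange(.data$presented_duration, .data$order_condition)
}
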