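# CSV schemas: durations are written in seconds at full double precision
# (>= 6 decimal digits).

#' Read and write trial-level and result CSV files
#'
#' Readers and writers for the package's rectangular interchange formats:
#'
#' * production trials: `participant_id,order_condition,trial_index,`
#'   `produced_duration_s`;
#' * reproduction trials: `participant_id,order_condition,block,`
#'   `trial_index,presented_duration_s,reproduced_duration_s`;
#' * per-participant measures: `participant_id,n_analyzed,`
#'   `mean_production_s,sd_s,drift_slope_s_per_trial,drift_intercept_s,`
#'   `rmsr_s,scaled_rmsr`;
#' * central-tendency fits: `participant_id,slope,intercept_s,`
#'   `n_trials_used`;
#' * ground-truth participant parameters (one row per participant).
#'
#' Writers take the in-memory tibbles produced by the package; readers
#' return them.
#'
#' @param trials,measures,fits,params In-memory tibbles.
#' @param path File path.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name clockvar_io
NULL

#' @rdname clockvar_io
#' @export
write_production_csv <- function(trials, path) {
  out <- dplyr::rename(trials, produced_duration_s = "produced_duration")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname clockvar_io
#' @export
read_production_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    order_condition = readr::col_character(),
                    trial_index = readr::col_integer(),
                    produced_duration_s = readr::col_double()
                  )) |>
    dplyr::rename(produced_duration = "produced_duration_s")
}

#' @rdname clockvar_io
#' @export
write_reproduction_csv <- function(trials, path) {
  out <- dplyr::rename(trials,
                       presented_duration_s = "presented_duration",
                       reproduced_duration_s = "reproduced_duration")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname clockvar_io
#' @export
read_reproduction_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    order_condition = readr::col_character(),
                    block = readr::col_integer(),
                    trial_index = readr::col_integer(),
                    presented_duration_s = readr::col_double(),
                    reproduced_duration_s = readr::col_double()
                  )) |>
    dplyr::rename(presented_duration = "presented_duration_s",
                  reproduced_duration = "reproduced_duration_s")
}

#' @rdname clockvar_io
#' @export
write_measures_csv <- function(measures, path) {
  out <- dplyr::rename(measures,
                       mean_production_s = "mean_production",
                       sd_s = "sd",
                       drift_slope_s_per_trial = "drift_slope",
                       drift_intercept_s = "drift_intercept",
                       rmsr_s = "rmsr")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname clockvar_io
#' @export
read_measures_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(mean_production = "mean_production_s",
                  sd = "sd_s",
                  drift_slope = "drift_slope_s_per_trial",
                  drift_intercept = "drift_intercept_s",
                  rmsr = "rmsr_s")
}

#' @rdname clockvar_io
#' @export
write_fits_csv <- function(fits, path) {
  out <- dplyr::rename(fits, intercept_s = "intercept")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname clockvar_io
#' @export
read_fits_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(intercept = "intercept_s")
}

#' @rdname clockvar_io
#' @export
write_params_csv <- function(params, path) {
  readr::write_csv(params, path)
  invisible(path)
}

#' @rdname clockvar_io
#' @export
read_params_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    order_condition = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Read or write a pipeline configuration file
#'
#' Configurations are stored as flat YAML (`key: value`); see
#' [pipeline_config()] for the keys and defaults.
#'
#' @param config A [pipeline_config()] list.
#' @param path File path.
#' @return `read_config()` returns a validated [pipeline_config()];
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  flat <- unclass(config)
  flat$design <- unclass(flat$design)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design)) {
    raw$design <- do.call(task_design, raw$design)
  }
  do.call(pipeline_config, raw)
}
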