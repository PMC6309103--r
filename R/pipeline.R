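#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one validated list:
#' task shape, screening and filtering thresholds, centering reference,
#' generator hyperparameters, seeds, and Bayes-factor settings. Defaults
#' reproduce the standard study conditions: 20 production trials with 2
#' start-up trials removed, exclusion of participants producing > 3 s
#' intervals on 5 or more analyzed trials, reproduction outlier bounds of
#' 0.5 and 2.5 s, and centering at 1.4 s.
#'
#' @param n_participants Cohort size when the generator is enabled.
#' @param seed Integer seed governing every random stage.
#' @param generator Use the synthetic-data generator (`TRUE`) or read trial
#'   CSVs from `production_csv` / `reproduction_csv` (`FALSE`).
#' @param hyperparams Generator hyperparameters, see [cohort_hyperparams()].
#' @param design Reproduction [task_design()].
#' @param n_trials,n_startup Production-session shape.
#' @param screening_limit,screening_min_count Aberrant-producer rule, see
#'   [screen_participants()].
#' @param outlier_low,outlier_high Reproduction outlier bounds (seconds).
#' @param center_reference Centering reference duration (seconds).
#' @param production_csv,reproduction_csv Input paths when
#'   `generator = FALSE`.
#' @param bf_backend `"quadrature"` or `"bic"`, see [bf_model_comparison()].
#' @param prior_scale_ttest,prior_scale_fixed,prior_scale_random,correlation_kappa
#'   Prior widths for the Bayes-factor stages.
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(n_participants = 10, seed = 1)
#' validate_config(cfg)
#' @export
pipeline_config <- function(n_participants = 63L,
                            seed = 1L,
                            generator = TRUE,
                            hyperparams = cohort_hyperparams(),
                            design = task_design(),
                            n_trials = 20L,
                            n_startup = 2L,
                            screening_limit = 3,
                            screening_min_count = 5L,
                            outlier_low = 0.5,
                            outlier_high = 2.5,
                            center_reference = 1.4,
                            production_csv = NULL,
                            reproduction_csv = NULL,
                            bf_backend = "quadrature",
                            prior_scale_ttest = sqrt(2) / 2,
                            prior_scale_fixed = sqrt(2) / 4,
                            prior_scale_random = 1,
                            correlation_kappa = 1) {
  structure(
    list(n_participants = as.integer(n_participants),
         seed = as.integer(seed),
         generator = isTRUE(generator),
         hyperparams = hyperparams,
         design = design,
         n_trials = as.integer(n_trials),
         n_startup = as.integer(n_startup),
         screening_limit = screening_limit,
         screening_min_count = as.integer(screening_min_count),
         outlier_low = outlier_low,
         outlier_high = outlier_high,
         center_reference = center_reference,
         production_csv = production_csv,
         reproduction_csv = reproduction_csv,
         bf_backend = bf_backend,
         prior_scale_ttest = prior_scale_ttest,
         prior_scale_fixed = prior_scale_fixed,
         prior_scale_random = prior_scale_random,
         correlation_kappa = correlation_kappa),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Checks every invariant of [pipeline_config()] and returns all violations
#' found (an empty character vector means the configuration is valid). Each
#' violation names the offending key and the constraint.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violation messages.
#' @export
validate_config <- function(config) {
  v <- character()
  add <- function(v, cond, msg) if (!isTRUE(cond)) c(v, msg) else v
  v <- add(v, config$n_participants >= 0,
           "n_participants: must be >= 0")
  v <- add(v, is.finite(config$seed), "seed: must be a finite integer")
  v <- add(v, config$n_trials > config$n_startup,
           "n_trials: must exceed n_startup")
  v <- add(v, config$n_startup >= 0, "n_startup: must be >= 0")
  v <- add(v, config$screening_limit > 0,
           "screening_limit: must be positive")
  v <- add(v, config$screening_min_count >= 1,
           "screening_min_count: must be >= 1")
  v <- add(v, config$outlier_low > 0 &&
             config$outlier_low < config$outlier_high,
           "outlier bounds: need 0 < outlier_low < outlier_high")
  v <- add(v, config$center_reference > 0,
           "center_reference: must be positive")
  v <- add(v, inherits(config$design, "task_design"),
           "design: must be a task_design()")
  v <- add(v, config$bf_backend %in% c("quadrature", "bic"),
           "bf_backend: must be 'quadrature' or 'bic'")
  v <- add(v, config$prior_scale_ttest > 0,
           "prior_scale_ttest: must be positive")
  v <- add(v, config$prior_scale_fixed > 0,
           "prior_scale_fixed: must be positive")
  v <- add(v, config$prior_scale_random > 0,
           "prior_scale_random: must be positive")
  v <- add(v, config$correlation_kappa > 0,
           "correlation_kappa: must be positive")
  if (!config$generator) {
    v <- add(v, !is.null(config$production_csv) &&
               !is.null(config$reproduction_csv),
             paste0("production_csv/reproduction_csv: required when the ",
                    "generator is disabled"))
  }
  v
}

#' Run the full clock-variability analysis
#'
#' Executes the pipeline end to end: obtain trial data (synthetic or from
#' CSV), remove production start-up trials, screen aberrant producers,
#' compute per-participant variability measures and the drift t test,
#' filter reproduction outliers, compute condition means, center durations,
#' fit per-participant central-tendency slopes, correlate the scaled RMSR
#' with the slopes, and compare nested mixed models for the centered
#' reproductions. Deterministic given the configuration seed.
#'
#' @param config A valid [pipeline_config()].
#' @param out_dir Optional directory; when given, all per-stage CSV
#'   artifacts and a plain-text report are written there.
#' @return A list of class `analysis_report`; see the package vignette for
#'   the component-by-component description.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid configuration:\n  ",
         paste(violations, collapse = "\n  "), call. = FALSE)
  }
  withr::local_seed(config$seed)

  # stage: input
  if (config$generator) {
    participants <- sample_participants(config$n_participants,
                                        config$hyperparams, seed = NULL)
    if (nrow(participants) == 0L) {
      stop("stage input: generator produced an empty cohort", call. = FALSE)
    }
    cohort <- simulate_cohort(participants, design = config$design,
                              n_trials = config$n_trials,
                              n_startup = config$n_startup, seed = NULL)
    production <- cohort$production
    reproduction <- cohort$reproduction
  } else {
    participants <- NULL
    production <- read_production_csv(config$production_csv)
    reproduction <- read_reproduction_csv(config$reproduction_csv)
    if (nrow(production) == 0L || nrow(reproduction) == 0L) {
      stop("stage input: empty trial data", call. = FALSE)
    }
  }

  # stage: production metrics
  analyzed <- remove_startup(production, config$n_startup)
  screening <- screen_participants(analyzed, config$screening_limit,
                                   config$screening_min_count)
  kept <- analyzed[analyzed$participant_id %in% screening$kept_ids, ]
  measures <- production_measures(kept)
  drift_bf <- bf_one_sample(abs(measures$drift_slope), null_value = 0,
                            prior_scale = config$prior_scale_ttest)

  # stage: reproduction metrics
  repro_kept <- reproduction[
    reproduction$participant_id %in% screening$kept_ids, ]
  filt <- filter_outliers(repro_kept, config$outlier_low,
                          config$outlier_high)
  cond_means <- condition_means(filt$trials)
  centered <- center_durations(filt$trials, config$center_reference)
  fits <- central_tendency_fits(centered)

  # stage: measure-vs-slope validation
  joined <- dplyr::inner_join(measures, fits, by = "participant_id")
  correlation <- bf_correlation(joined$scaled_rmsr, joined$slope,
                                kappa = config$correlation_kappa)

  # stage: model comparison
  model_data <- centered |>
    dplyr::inner_join(
      dplyr::select(measures, "participant_id", measure = "scaled_rmsr"),
      by = "participant_id")
  models <- list(
    model_spec("intercept only", character()),
    model_spec("duration", "presented_duration"),
    model_spec("duration + order", c("presented_duration", "order")),
    model_spec("duration + measure",
               c("presented_duration", "measure",
                 "measure:presented_duration")),
    model_spec("duration + order + measure",
               c("presented_duration", "order", "measure",
                 "measure:presented_duration"))
  )
  comparison <- bf_model_comparison(model_data, models,
                                    prior_scale_fixed =
                                      config$prior_scale_fixed,
                                    prior_scale_random =
                                      config$prior_scale_random,
                                    backend = config$bf_backend)

  report <- structure(
    list(participants = participants,
         production = production,
         reproduction = reproduction,
         screening = screening,
         measures = measures,
         drift_bf = drift_bf,
         filter_summary = filt$summary,
         condition_means = cond_means,
         fits = fits,
         joined = joined,
         correlation = correlation,
         model_comparison = comparison,
         provenance = list(
           config_hash = rlang::hash(unclass(config)),
           seed = config$seed,
           package_version =
             as.character(utils::packageVersion("clockvar")))),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Format an analysis report as plain text
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @return Character vector of report lines (no timestamps, so identical
#'   runs format identically).
#' @export
format_report <- function(report) {
  scr <- report$screening
  cmp <- report$model_comparison$models
  corr <- report$correlation
  c(
    "clock variability analysis report",
    "=================================",
    sprintf("provenance: config %s, seed %d, clockvar %s",
            report$provenance$config_hash, report$provenance$seed,
            report$provenance$package_version),
    "",
    sprintf("participants: %d kept, %d excluded by screening (> %g s on >= %d trials)",
            length(scr$kept_ids), length(scr$excluded_ids), scr$limit,
            scr$min_count),
    sprintf("reproduction outliers removed: %d of %d (%.2f%%)",
            report$filter_summary$n_removed, report$filter_summary$n_input,
            100 * report$filter_summary$proportion_removed),
    "",
    sprintf("mean production: %.3f s; mean scaled RMSR: %.4f",
            mean(report$measures$mean_production),
            mean(report$measures$scaled_rmsr)),
    sprintf("drift (one-sample BF on |slopes|): BF10 = %.4g (%s)",
            report$drift_bf$bf10, report$drift_bf$interpretation),
    sprintf("mean central-tendency slope: %.3f",
            mean(report$joined$slope)),
    sprintf("scaled RMSR vs slope: r = %.3f, BF10 = %.4g, posterior median %.3f, MAD %.3f, %d%% CI (%.3f, %.3f)",
            corr$r, corr$bf10, corr$posterior_median_r, corr$posterior_mad,
            round(100 * corr$ci_level), corr$credible_interval[1],
            corr$credible_interval[2]),
    "",
    "model comparison (vs first model):",
    sprintf("  %-28s logML %12.2f  log10 BF %9.2f  %s",
            cmp$name, cmp$log_ml,
            (cmp$log_ml - cmp$log_ml[1]) / log(10), cmp$label)
  )
}

#' Write all report artifacts to a directory
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(report$participants)) {
    write_params_csv(report$participants, p("ground_truth_params.csv"))
  }
  write_production_csv(report$production, p("production_trials.csv"))
  write_reproduction_csv(report$reproduction, p("reproduction_trials.csv"))
  write_measures_csv(report$measures, p("production_measures.csv"))
  write_fits_csv(report$fits, p("central_tendency_fits.csv"))
  readr::write_csv(report$screening$counts, p("screening.csv"))
  readr::write_csv(report$condition_means, p("condition_means.csv"))
  readr::write_csv(report$model_comparison$models, p("model_comparison.csv"))
  writeLines(format_report(report), p("report.txt"))
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Scatter of clock-variability measure against central-tendency slope
#'
#' Optional figure helper (requires ggplot2): per-participant scaled RMSR
#' against the fitted central-tendency slope, with an OLS trend line.
#'
#' @param joined The `joined` component of an `analysis_report`.
#' @return A ggplot object.
#' @export
plot_measure_vs_slope <- function(joined) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(joined,
                  ggplot2::aes(x = .data$slope, y = .data$scaled_rmsr)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", color = "grey30") +
    ggplot2::labs(x = "central-tendency slope",
                  y = "scaled RMSR (clock-noise index)")
}
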