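noise_free <- function(...) {
  participant_params("nf", clock_cv = 0, drift_slope = 0,
                     startup_mean_factor = 1, startup_cv_factor = 1,
                     motor_cv = 0, ...)
}

test_that("noise-free production reproduces the internal 1-s representation", {
  trials <- simulate_production(noise_free(mu_one_second = 1.1), 20, 2,
                                seed = 1)
  expect_equal(nrow(trials), 20)
  expect_equal(trials$produced_duration, rep(1.1, 20))
  expect_equal(trials$trial_index, 1:20)
})

test_that("start-up trials are mean-inflated and analyzed trials follow the drift", {
  p <- participant_params("x", clock_cv = 0, drift_slope = 0.01,
                          mu_one_second = 1, motor_cv = 0)
  trials <- simulate_production(p, 20, 2, seed = 1)
  expect_equal(trials$produced_duration[1:2], rep(1 * 1.8, 2))
  expect_equal(trials$produced_duration[3:20], 1 + 0.01 * (1:18))
})

test_that("production simulation is seeded and guards impossible drifts", {
  p <- participant_params("x", clock_cv = 0.1)
  expect_identical(simulate_production(p, seed = 3),
                   simulate_production(p, seed = 3))
  bad <- participant_params("x", mu_one_second = 0.5, drift_slope = -0.1)
  expect_error(simulate_production(bad, 20, 2, seed = 1),
               "non-positive mean production at trial")
  expect_error(simulate_production(p, n_trials = 5, n_startup = 6),
               "n_trials >= n_startup")
})

test_that("pooled production noise obeys the scalar property", {
  p <- participant_params("x", clock_cv = 0.1, mu_one_second = 1,
                          drift_slope = 0)
  trials <- simulate_production(p, n_trials = 100002, n_startup = 2,
                                seed = 21)
  analyzed <- trials$produced_duration[-(1:2)]
  expect_lt(abs(sd(analyzed) - 0.1) / 0.1, 0.02)
  expect_lt(abs(sd(analyzed) / mean(analyzed) - 0.1) / 0.1, 0.02)
})

test_that("noise-free observers reproduce presented durations exactly", {
  trials <- simulate_reproduction(noise_free(), seed = 5)
  expect_equal(trials$reproduced_duration, trials$presented_duration)
})

test_that("a vanishing prior width forces reproductions onto the prior mean", {
  p <- participant_params("x", clock_cv = 0.1, motor_cv = 0,
                          prior_sd = 1e-9, prior_mean = 1.4)
  trials <- simulate_reproduction(p, seed = 5)
  expect_true(all(abs(trials$reproduced_duration - 1.4) < 1e-6))
})

test_that("every block presents each duration level equally often", {
  trials <- simulate_reproduction(participant_params("x"), seed = 9)
  tab <- table(trials$block, trials$presented_duration)
  expect_true(all(tab == 40))
  expect_equal(dim(tab), c(2L, 3L))
  expect_error(task_design(trials_per_block = 100,
                           duration_levels = c(1, 1.5, 2)),
               "not divisible")
})

test_that("the analytic expected slope has its limiting values", {
  expect_equal(expected_central_slope(noise_free()), 1)
  huge <- participant_params("x", clock_cv = 1e6)
  expect_lt(expected_central_slope(huge), 1e-6)
  expect_error(expected_central_slope(participant_params("x"),
                                      duration_levels = 1.4),
               "2 distinct")
})

test_that("the analytic slope is strictly decreasing in clock noise and bounded", {
  cvs <- seq(0, 1, by = 0.05)
  slopes <- vapply(cvs, function(cv) {
    expected_central_slope(participant_params("x", clock_cv = cv))
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
  expect_true(all(slopes > 0 & slopes <= 1 + 1e-12))
})

test_that("Monte-Carlo mean slope matches the analytic oracle", {
  p <- participant_params("x", clock_cv = 0.15, prior_sd = 0.25)
  slopes <- mc_central_slope(p, n_sessions = 5000, seed = 31)
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - expected_central_slope(p)), 3 * se)
})

test_that("higher clock noise yields smaller Monte-Carlo slopes", {
  lo <- mc_central_slope(participant_params("x", clock_cv = 0.1),
                         n_sessions = 2000, seed = 41)
  hi <- mc_central_slope(participant_params("x", clock_cv = 0.2),
                         n_sessions = 2000, seed = 42)
  expect_lt(mean(hi), mean(lo))
})

test_that("cohort simulation is reproducible and carries both tasks", {
  parts <- sample_participants(3, seed = 2)
  a <- simulate_cohort(parts, seed = 8)
  b <- simulate_cohort(parts, seed = 8)
  expect_identical(a, b)
  expect_equal(nrow(a$production), 3 * 20)
  expect_equal(nrow(a$reproduction), 3 * 240)
})
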