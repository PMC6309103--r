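production_tbl <- function(durations, id = "P001") {
  tibble::tibble(participant_id = id,
                 order_condition = "production_first",
                 trial_index = seq_along(durations),
                 produced_duration = durations)
}

test_that("start-up removal drops the first trials and recodes indices 1..k", {
  trials <- production_tbl(seq(1, 2, length.out = 20))
  out <- remove_startup(trials, 2)
  expect_equal(nrow(out), 18)
  expect_equal(out$trial_index, 1:18)
  expect_equal(out$produced_duration, trials$produced_duration[3:20])

  same <- remove_startup(trials, 0)
  expect_equal(same$produced_duration, trials$produced_duration)
  expect_equal(same$trial_index, 1:20)

  expect_error(remove_startup(production_tbl(c(1, 1)), 2), "P001")
})

test_that("aberrant producers are excluded by the over-limit rule", {
  long5 <- production_tbl(c(rep(1, 13), rep(3.2, 5)), "A")
  ok <- production_tbl(rep(c(0.9, 1.1, 2.9), 6), "B")
  long4 <- production_tbl(c(rep(1, 14), rep(3.2, 4)), "C")
  boundary <- production_tbl(rep(3.0, 18), "D")  # exactly at the limit
  rep_all <- dplyr::bind_rows(long5, ok, long4, boundary)
  scr <- screen_participants(rep_all)
  expect_equal(scr$excluded_ids, "A")
  expect_setequal(scr$kept_ids, c("B", "C", "D"))
  expect_length(intersect(scr$kept_ids, scr$excluded_ids), 0)
  expect_setequal(c(scr$kept_ids, scr$excluded_ids),
                  unique(rep_all$participant_id))
  expect_equal(scr$counts$n_over_limit[scr$counts$participant_id == "A"], 5)
})

test_that("summary measures are exact for degenerate and linear series", {
  const <- production_summary(production_tbl(rep(1, 18)))
  expect_equal(const$sd, 0)
  expect_equal(const$drift_slope, 0)
  expect_equal(const$rmsr, 0)
  expect_equal(const$scaled_rmsr, 0)

  # perfect line: all variation is drift, so rmsr = 0 while sd = |slope| * sd(1:18)
  line <- production_summary(production_tbl(2 - 0.05 * (1:18)))
  expect_equal(line$rmsr, 0, tolerance = 1e-10)
  expect_equal(line$drift_slope, -0.05, tolerance = 1e-10)
  expect_equal(line$sd, 0.05 * sqrt(28.5), tolerance = 1e-12)
})

test_that("summary measures match a brute-force normal-equations oracle", {
  y <- c(1.0, 1.2, 0.8, 1.0)
  got <- production_summary(production_tbl(y))
  oracle <- ols_bruteforce(1:4, y)
  expect_equal(got$rmsr, oracle$rmsr, tolerance = 1e-10)
  expect_equal(got$drift_slope, oracle$slope, tolerance = 1e-10)
  expect_equal(got$drift_intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(got$scaled_rmsr, oracle$rmsr / mean(y), tolerance = 1e-10)
})

test_that("summaries refuse unusable inputs", {
  expect_error(production_summary(production_tbl(c(1, 1.1))),
               "insufficient")
  expect_error(production_summary(production_tbl(c(1, -1, 1, 1))),
               "positive")
  two <- dplyr::bind_rows(production_tbl(rep(1, 5), "A"),
                          production_tbl(rep(1, 5), "B"))
  expect_error(production_summary(two), "one participant")
  expect_warning(
    out <- production_measures(dplyr::bind_rows(
      production_tbl(rep(1, 5), "A"), production_tbl(c(1, 1.1), "B"))),
    "dropping participant B")
  expect_equal(out$participant_id, "A")
})

test_that("rmsr never exceeds sd and both scale linearly with the data", {
  withr::local_seed(13)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    y <- exp(rnorm(n, 0, 0.3))
    s <- production_summary(production_tbl(y))
    expect_lte(s$rmsr, s$sd + 1e-12)
    k <- runif(1, 0.5, 3)
    sk <- production_summary(production_tbl(k * y))
    expect_equal(sk$mean_production, k * s$mean_production)
    expect_equal(sk$sd, k * s$sd)
    expect_equal(sk$rmsr, k * s$rmsr)
    expect_equal(sk$scaled_rmsr, s$scaled_rmsr, tolerance = 1e-12)
  }
})

test_that("drift widens the gap between sd and rmsr monotonically", {
  gap_at_slope <- function(slope, seed) {
    withr::local_seed(seed)
    gaps <- replicate(500, {
      p <- participant_params("x", clock_cv = 0.1, drift_slope = slope,
                              mu_one_second = 1.2)
      s <- production_summary(
        remove_startup(simulate_production(p, 20, 2, seed = NULL)))
      s$sd - s$rmsr
    })
    mean(gaps)
  }
  gaps <- c(gap_at_slope(0, 51), gap_at_slope(0.02, 52),
            gap_at_slope(0.05, 53))
  expect_true(all(diff(gaps) > 0))
  expect_gt(gaps[2], 0)
})

test_that("drift-free rmsr and sd estimate the same noise level", {
  # with the default denominators (n-1 for sd, n for rmsr) the two means
  # differ by the analytic chi-expectation ratio at n = 18; after df
  # correction of the rmsr they agree within 2%
  withr::local_seed(61)
  n <- 18
  p <- participant_params("x", clock_cv = 0.1, drift_slope = 0)
  sims <- replicate(2000, {
    trials <- remove_startup(simulate_production(p, 20, 2, seed = NULL))
    c(production_summary(trials)$sd,
      production_summary(trials)$rmsr,
      production_summary(trials, rmsr_denominator = "n-2")$rmsr)
  })
  c4 <- sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
  chi_n <- sqrt(2 / n) * exp(lgamma((n - 1) / 2) - lgamma((n - 2) / 2))
  expect_equal(mean(sims[2, ]) / mean(sims[1, ]), chi_n / c4,
               tolerance = 0.01)
  expect_lt(abs(mean(sims[1, ]) - mean(sims[3, ])) / mean(sims[1, ]), 0.02)
  expect_equal(sims[3, ], sims[2, ] * sqrt(n / (n - 2)), tolerance = 1e-12)
})

test_that("mean scaled rmsr recovers clock_cv at its exact finite-sample expectation", {
  withr::local_seed(71)
  cv <- 0.1; n <- 18
  p <- participant_params("x", clock_cv = cv, mu_one_second = 1,
                          drift_slope = 0)
  sr <- replicate(3000, {
    production_summary(
      remove_startup(simulate_production(p, 20, 2, seed = NULL)))$scaled_rmsr
  })
  # E[rmsr] = sigma * sqrt(2/n) * Gamma((n-1)/2) / Gamma((n-2)/2) for an OLS
  # fit with chi^2_{n-2} residual sum of squares; E[1/mean] adds (1 + cv^2/n)
  chi_mean <- sqrt(2 / n) * exp(lgamma((n - 1) / 2) - lgamma((n - 2) / 2))
  target <- cv * chi_mean * (1 + cv^2 / n)
  se <- sd(sr) / sqrt(length(sr))
  expect_lt(abs(mean(sr) - target), 3 * se)
})
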