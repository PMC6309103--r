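test_that("evidence labels follow the Jeffreys bands with inversion below 1", {
  expect_equal(interpret_bf(1), "inconclusive")
  expect_equal(interpret_bf(2.23), "anecdotal evidence for H1")
  expect_equal(interpret_bf(1 / 2.23), "anecdotal evidence for H0")
  expect_equal(interpret_bf(5), "moderate evidence for H1")
  expect_equal(interpret_bf(25), "strong evidence for H1")
  expect_equal(interpret_bf(0.02), "very strong evidence for H0")
  expect_equal(interpret_bf(325.58), "extreme evidence for H1")
  expect_error(interpret_bf(-1), "positive")
})

test_that("the one-sample JZS Bayes factor favors the null at t = 0", {
  x <- make_x_with_t(20, 0)
  res <- bf_one_sample(x, null_value = 0)
  expect_lt(res$bf10, 1)
  expect_gt(res$bf10, 0)
  expect_equal(res$log_bf10, log(res$bf10))
})

test_that("the one-sample Bayes factor is scale invariant about the null", {
  x <- make_x_with_t(25, 2.2) + 0  # mean shifted data, null at 0
  a <- bf_one_sample(x, 0)
  b <- bf_one_sample(3.7 * x, 0)
  expect_equal(a$bf10, b$bf10, tolerance = 1e-8)
})

test_that("the one-sample Bayes factor is monotone in |t| at fixed n", {
  bfs <- vapply(c(0, 0.5, 1, 2, 4, 6), function(t) {
    bf_one_sample(make_x_with_t(30, t), 0)$bf10
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
  neg <- bf_one_sample(make_x_with_t(30, -3), 0)$bf10
  pos <- bf_one_sample(make_x_with_t(30, 3), 0)$bf10
  expect_equal(neg, pos, tolerance = 1e-8)
})

test_that("the one-sample Bayes factor matches a grid-quadrature oracle", {
  for (case in list(c(n = 50, t = 6), c(n = 20, t = 2.5),
                    c(n = 63, t = 0.8))) {
    got <- bf_one_sample(make_x_with_t(case[["n"]], case[["t"]]), 0)
    oracle <- jzs_bf_gridquad(case[["t"]], case[["n"]])
    expect_equal(got$bf10, oracle, tolerance = 1e-3)
    expect_lt(got$numerical_error, 1e-8)
  }
  expect_error(bf_one_sample(rep(1, 10), 0), "zero variance")
})

test_that("perfect association yields decisive correlation evidence", {
  x <- seq_len(20)
  res <- bf_correlation(x, x + 0.0 * x)
  expect_gt(res$bf10, 100)
  expect_gt(res$posterior_median_r, 0.99)
})

test_that("independent data yield a null-favoring correlation Bayes factor", {
  withr::local_seed(19)
  res <- bf_correlation(rnorm(1000), rnorm(1000))
  expect_lt(res$bf10, 1)
})

test_that("the correlation posterior matches an Euler-integral grid oracle", {
  pr <- make_pair_with_r(63, -0.45)
  got <- bf_correlation(pr$x, pr$y)
  oracle <- corr_bf_oracle(-0.45, 63)
  expect_equal(got$r, -0.45, tolerance = 1e-12)
  expect_equal(got$bf10, oracle$bf10, tolerance = 1e-3)
  expect_lt(abs(got$posterior_median_r - oracle$median), 1e-3)
  expect_lt(abs(got$posterior_mad - oracle$mad), 1e-3)
  expect_lt(max(abs(got$credible_interval - oracle$ci90)), 1e-3)
  expect_lte(got$credible_interval[1], got$posterior_median_r)
  expect_gte(got$credible_interval[2], got$posterior_median_r)
  expect_error(bf_correlation(rep(1, 10), rnorm(10)), "constant")
})

test_that("model specifications enforce their term grammar", {
  expect_error(model_spec("m", "banana"), "unknown fixed term")
  expect_error(model_spec("m", "measure:presented_duration"),
               "requires both main effects")
  m <- model_spec("m", c("presented_duration", "measure",
                         "measure:presented_duration"))
  expect_true("intercept" %in% m$fixed_terms)
})

test_that("identical model specs compare at exactly BF = 1 and BFs are transitive", {
  md <- cohort_model_data(n = 15, seed = 301)
  dup <- bf_model_comparison(md, list(
    model_spec("a", "presented_duration"),
    model_spec("b", "presented_duration")))
  expect_identical(dup$pairwise_bf["a", "b"], 1)

  cmp <- bf_model_comparison(md, list(
    model_spec("null", character()),
    model_spec("dur", "presented_duration"),
    model_spec("dur+meas", c("presented_duration", "measure",
                             "measure:presented_duration"))))
  lp <- cmp$log_pairwise_bf
  expect_lt(abs(lp["null", "dur+meas"] -
                  (lp["null", "dur"] + lp["dur", "dur+meas"])), 1e-10)
  expect_true(all(is.finite(cmp$models$log_ml)))
})

test_that("non-nested model sets are rejected", {
  md <- cohort_model_data(n = 10, seed = 302)
  expect_error(bf_model_comparison(md, list(
    model_spec("a", c("presented_duration", "order")),
    model_spec("b", c("presented_duration", "measure")))),
    "does not nest")
})

test_that("quadrature and BIC backends agree on the direction of evidence", {
  md <- cohort_model_data(n = 20, seed = 303)
  models <- list(model_spec("dur", "presented_duration"),
                 model_spec("dur+meas",
                            c("presented_duration", "measure",
                              "measure:presented_duration")))
  quad <- bf_model_comparison(md, models)
  bic <- suppressMessages(bf_model_comparison(md, models, backend = "bic"))
  expect_equal(sign(diff(quad$models$log_ml)),
               sign(diff(bic$models$log_ml)))
})

test_that("the measure-bearing model wins when clock noise varies across participants", {
  for (i in 1:3) {
    md <- cohort_model_data(n = 40, seed = 310 + i)
    cmp <- bf_model_comparison(md, list(
      model_spec("dur", "presented_duration"),
      model_spec("dur+meas", c("presented_duration", "measure",
                               "measure:presented_duration"))))
    expect_gt(cmp$pairwise_bf["dur+meas", "dur"], 10)
  }
})
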