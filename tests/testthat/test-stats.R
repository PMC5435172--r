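test_that("ols_fit recovers exact and degenerate lines", {
  fit <- suppressWarnings(ols_fit(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  flat <- suppressWarnings(ols_fit(c(1, 2, 3), c(3, 3, 3)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  set.seed(61)
  x <- stats::runif(100, 1, 10)
  y <- 2 * x + stats::rnorm(100, 0, 0.01)
  expect_gt(ols_fit(x, y)$slope, 1.99)
  expect_lt(ols_fit(x, y)$slope, 2.01)

  expect_error(ols_fit(rep(1, 5), 1:5), "degenerate")
  expect_error(ols_fit(1:2, 1:2), "at least 3")
})

test_that("ols_fit matches brute-force normal equations to 1e-10", {
  set.seed(62)
  for (rep in 1:100) {
    n <- sample(3:30, 1)
    x <- stats::rnorm(n, sd = stats::runif(1, 0.5, 5))
    y <- stats::runif(1, -2, 2) * x + stats::rnorm(n)
    through <- rep %% 2 == 0
    if (stats::var(x) == 0) next
    got <- ols_fit(x, y, through_origin = through)
    want <- brute_force_ols(x, y, through_origin = through)
    for (f in c("slope", "r_squared", "f_statistic", "f_pvalue",
                "t_statistic_slope", "t_pvalue_slope")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
    }
    if (!through) expect_equal(got$intercept, want$intercept,
                               tolerance = 1e-10)
  }
})

test_that("power_fit identifies exact power laws on the log-log scale", {
  x <- c(1, 2, 4, 9, 16, 30)
  fit <- suppressWarnings(power_fit(x, 2 * sqrt(x)))
  expect_equal(fit$coef_a, 2, tolerance = 1e-12)
  expect_equal(fit$coef_b, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$r_squared_linear, 1, tolerance = 1e-12)

  const <- suppressWarnings(power_fit(x, rep(3, 6)))
  expect_equal(const$coef_b, 0)
  expect_error(power_fit(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("increase statistic matches its closed form on exact series", {
  # geometric series ratio 0.96: every pair gives 100 * (1 - r)
  rec <- record_from_mlom_sums(c(10, 9.6, 9.216))
  out <- mlom_increase_statistic(list(rec))
  expect_equal(out$mean_pct, 4, tolerance = 1e-12)
  expect_equal(out$sd_pct, 0, tolerance = 1e-12)
  expect_identical(out$n_pairs, 2L)

  expect_equal(mlom_increase_statistic(
    list(record_from_mlom_sums(c(10, 10))))$mean_pct, 0)
  expect_equal(mlom_increase_statistic(
    list(record_from_mlom_sums(c(10, 12))))$mean_pct, -20)

  set.seed(63)
  for (rep in 1:10) {
    r <- stats::runif(1, 0.7, 0.99)
    n <- sample(3:20, 1)
    rec <- record_from_mlom_sums(8 * r^(0:(n - 1)))
    out <- mlom_increase_statistic(list(rec))
    expect_equal(out$mean_pct, 100 * (1 - r), tolerance = 1e-9)
    expect_equal(out$sd_pct, 0, tolerance = 1e-9)
  }
})

test_that("increase statistic pools pairs and skips zero denominators", {
  recs <- list(record_from_mlom_sums(c(10, 9.6), "a"),
               record_from_mlom_sums(c(10, 12), "b"),
               record_from_mlom_sums(c(0, 5, 4), "c"))
  out <- mlom_increase_statistic(recs)
  expect_identical(out$n_pairs, 3L)  # the 0 -> 5 pair is skipped
  expect_identical(out$n_skipped, 1L)
  expect_equal(out$mean_pct, mean(c(4, -20, 20)))
  expect_identical(nrow(out$per_specimen), 3L)
})

test_that("AMU comparison applies strict 20% and 50% thresholds", {
  recs <- list(
    record_from_mlom_sums(c(8, 7), "a", amu = 12.1),   # ratio 1.5125
    record_from_mlom_sums(c(8, 7), "b", amu = 9),      # ratio 1.125
    record_from_mlom_sums(c(8, 7), "c", amu = 12))     # ratio exactly 1.5
  out <- amu_comparison(recs)
  expect_identical(out$n_eligible, 3L)
  expect_identical(out$count_gt20, 2L)
  expect_identical(out$count_gt50, 1L)
  expect_lte(out$count_gt50, out$count_gt20)

  # adding a ratio-1.3 specimen increments the 20% count only
  out2 <- amu_comparison(c(recs, list(
    record_from_mlom_sums(c(10, 9), "d", amu = 13))))
  expect_identical(out2$count_gt20, out$count_gt20 + 1L)
  expect_identical(out2$count_gt50, out$count_gt50)
})

test_that("module numbers normalize to body-axis positions", {
  expect_equal(normalized_module_number(5, 20, 40), 10)
  expect_equal(normalized_module_number(20, 20, 40), 40)
  expect_equal(normalized_module_number(1, 1, 7.5), 7.5)
  expect_error(normalized_module_number(21, 20, 40), "out of range")
})

test_that("moving averages reduce length by window - 1", {
  expect_equal(moving_average(c(1, 3)), 2)
  expect_equal(moving_average(c(1, 2, 3, 4), 2), c(1.5, 2.5, 3.5))
  expect_equal(moving_average(rep(7, 5), 3), rep(7, 3))
  expect_error(moving_average(c(1, 2), 3), "window")
})

test_that("population summaries assemble every statistic deterministically", {
  pop <- generate_population(60, growth_params(rng_seed = 64,
                                               n_vertices = 512L))
  recs <- measure_population(pop, delta = 0.5)
  s1 <- summarize_population(recs)
  s2 <- summarize_population(recs)
  expect_identical(s1, s2)

  expect_identical(s1$n_total, 60L)
  expect_lte(s1$amu_gt50_count, s1$amu_gt20_count)
  expect_lte(s1$amu_gt20_count, s1$amu_n_eligible)
  expect_lte(s1$amu_n_eligible, s1$n_total)
  expect_true(s1$tl_min <= s1$tl_mean && s1$tl_mean <= s1$tl_max)
  expect_s3_class(s1$lw_regression, "regression_result")
  expect_identical(s1$lw_regression_origin$model_form,
                   "linear_through_origin")
  expect_error(summarize_population(recs[1:2]), "at least 3")
})
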