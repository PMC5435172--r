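test_that("posterior censoring counts modules above the grain limit", {
  expect_identical(dickinsonia:::censored_module_count(
    c(2.0, 1.5, 0.4, 0.2), 0.5), 2L)
  expect_identical(dickinsonia:::censored_module_count(
    c(2.0, 1.5, 0.4, 0.2), 0), 4L)
  expect_identical(dickinsonia:::censored_module_count(
    c(2.0, 1.5, 0.4, 0.2), 5), 0L)
  # only contiguous posterior modules are stripped
  expect_identical(dickinsonia:::censored_module_count(
    c(2.0, 0.4, 1.5, 0.2), 0.5), 3L)
})

test_that("resolution limit yields monotone minimum counts on specimens", {
  set.seed(41)
  s <- generate_specimen(20, noise_free_params())
  s0 <- apply_resolution_limit(s, 0)
  expect_identical(s0$n_modules_observed, s$n_modules_true)

  deltas <- c(0, 0.2, 0.5, 1, 2, 5, 1e3)
  counts <- vapply(deltas, function(d) {
    apply_resolution_limit(s, d)$n_modules_observed
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[length(counts)], 0L)
  expect_true(apply_resolution_limit(s, 1e3)$unmeasurable)
})

test_that("distortion is seeded, smooth and breaks bilateral symmetry", {
  set.seed(42)
  s <- generate_specimen(30, noise_free_params())

  identity_out <- apply_distortion(s, taphonomy_params())
  expect_identical(identity_out, s)

  tp <- taphonomy_params(distortion_sigma = 0.02 * 30, rng_seed = 5)
  d1 <- apply_distortion(s, tp)
  d2 <- apply_distortion(s, tp)
  expect_identical(d1, d2)
  expect_true(isTRUE(d1$generation$distorted))

  asym <- vapply(seq_len(s$n_modules_true), function(i) {
    abs(measure_mlom(d1, i, "left") - measure_mlom(d1, i, "right"))
  }, numeric(1))
  expect_gt(max(asym), 0)
})

test_that("size isometry survives mild distortion", {
  pop <- generate_population(500, growth_params(rng_seed = 8,
                                                n_vertices = 256L))
  distorted <- lapply(seq_along(pop), function(i) {
    s <- pop[[i]]
    apply_distortion(s, taphonomy_params(
      distortion_sigma = 0.01 * s$outline$total_length_mm,
      rng_seed = 1000 + i))
  })
  recs <- measure_population(distorted)
  tl <- vapply(recs, function(r) r$tl_mm, numeric(1))
  tw <- vapply(recs, function(r) r$tw_mm, numeric(1))
  expect_gte(ols_fit(tl, tw)$r_squared, 0.95)
})

test_that("completeness filtering is a seeded Bernoulli selection", {
  pop <- generate_population(40, growth_params(rng_seed = 3,
                                               n_vertices = 256L))
  all_in <- apply_completeness_filter(pop, taphonomy_params(completeness = 1))
  expect_length(all_in$complete, 40)
  none <- apply_completeness_filter(pop, taphonomy_params(completeness = 0))
  expect_length(none$complete, 0)
  expect_length(none$excluded, 40)
  expect_identical(none$excluded[[1]]$exclusion_reason,
                   "incomplete or deformed")

  # retention count lands inside the binomial 99% interval
  pop_big <- rep(pop, length.out = 988)
  pr <- 538 / 988
  kept <- length(apply_completeness_filter(
    pop_big, taphonomy_params(completeness = pr, rng_seed = 17))$complete)
  bounds <- stats::qbinom(c(0.005, 0.995), 988, pr)
  expect_gte(kept, bounds[1])
  expect_lte(kept, bounds[2])
})
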