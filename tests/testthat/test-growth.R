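test_that("width follows the width ratio exactly when noise is off", {
  # 21.06 / 24.31 = 0.8663: the ratio of the reference population means
  set.seed(21)
  s <- generate_specimen(24.31, noise_free_params(width_ratio = 0.8663))
  expect_equal(s$outline$total_width_mm, 21.06, tolerance = 0.01)
  expect_equal(measure_total_width(s) / measure_total_length(s), 0.8663,
               tolerance = 1e-6)
})

test_that("module count follows the scaling law without dispersion", {
  set.seed(22)
  s <- generate_specimen(25, noise_free_params(module_count_coeff = 3,
                                               module_count_exponent = 0.5))
  expect_identical(s$n_modules_true, 15L)  # round(3 * sqrt(25))
})

test_that("margin allocation is an exact normalized geometric series", {
  expect_equal(allocate_margin(100, 2, 0.5), c(200 / 3, 100 / 3))
  l <- allocate_margin(57.3, 9, 0.83)
  expect_equal(sum(l), 57.3)
  expect_equal(l[-1] / l[-9], rep(0.83, 8))
  expect_equal(allocate_margin(12, 1, 0.7), 12)
  expect_error(allocate_margin(10, 3, 1.2), "r must be")
})

test_that("noise-free specimens recover their construction parameters", {
  set.seed(23)
  r <- 0.96
  s <- generate_specimen(40, noise_free_params(mlom_decay_ratio = r))
  n <- s$n_modules_true

  mlm <- vapply(seq_len(n), function(i) measure_mlm(s, i), numeric(1))
  expect_lt(stats::sd(mlm) / mean(mlm), 0.01)

  mlom <- vapply(seq_len(n), function(i) measure_mlom(s, i), numeric(1))
  expect_true(all(diff(mlom) < 0))
  step_decrease <- 1 - mlom[-1] / mlom[-n]
  expect_equal(step_decrease, rep(1 - r, n - 1), tolerance = 0.02)
})

test_that("module width profiles are unimodal with a larger anterior end", {
  set.seed(24)
  for (tl in c(15, 40, 80)) {
    s <- generate_specimen(tl, noise_free_params())
    n <- s$n_modules_true
    expect_gte(n, 8)
    mw <- vapply(seq_len(n), function(i) measure_mw(s, i), numeric(1))
    signs <- sign(diff(mw))
    # one sign change: rises to a single interior maximum, then falls
    expect_equal(sum(diff(signs[signs != 0]) != 0), 1)
    expect_gt(which.max(mw), 1)
    expect_lt(which.max(mw), n)
    expect_gt(mw[1], mw[n])
  }
})

test_that("growth trajectories grow geometrically and add at the posterior", {
  p <- noise_free_params(growth_rate = 0.1, n_vertices = 512L)
  traj <- simulate_growth_trajectory(5, 20, p)
  tl <- vapply(traj, `[[`, numeric(1), "total_length_mm")
  n <- vapply(traj, `[[`, numeric(1), "n_modules_true")
  expect_equal(tl[length(tl)], 5 * 1.1^20, tolerance = 1e-10)
  expect_true(all(diff(tl) > 0))
  expect_true(all(diff(n) >= 0))
  expect_gt(n[length(n)], n[1])

  # dynamic counts agree with the static scaling law
  target <- p$module_count_coeff * tl^p$module_count_exponent
  expect_true(all(abs(n - target) <= 1))

  # anterior-indexed identity: each module's outer-margin length expands
  # consistently through life (pre-noise)
  for (t in seq_len(length(traj) - 1)) {
    s1 <- traj[[t]]$specimen
    s2 <- traj[[t + 1]]$specimen
    for (i in seq_len(min(s1$n_modules_true, s2$n_modules_true))) {
      expect_gte(measure_mlom(s2, i), measure_mlom(s1, i))
    }
  }
})

test_that("a newly inserted module ramps its midline length toward MLM", {
  p <- noise_free_params(growth_rate = 0.1, n_vertices = 512L)
  traj <- simulate_growth_trajectory(5, 20, p)
  ratios <- vapply(traj, function(sn) {
    measure_mlm(sn$specimen, sn$specimen$n_modules_true) / sn$mlm_mm
  }, numeric(1))
  expect_true(all(ratios <= 1.5 + 1e-9))
  # mid-ramp the growing posterior module is shorter than the others
  insertion_steps <- which(diff(vapply(traj, `[[`, numeric(1),
                                       "n_modules_true")) > 0) + 1
  expect_true(any(ratios[insertion_steps] < 1))
})

test_that("populations are seeded, reproducible and realistically sized", {
  p <- growth_params(rng_seed = 99, n_vertices = 512L)
  pop1 <- generate_population(60, p)
  pop2 <- generate_population(60, p)
  expect_identical(pop1, pop2)

  single <- generate_population(1, p)
  expect_length(single, 1)
  expect_identical(validate_specimen(single[[1]]), character(0))

  pop <- generate_population(500, growth_params(rng_seed = 7,
                                                n_vertices = 256L))
  tl <- vapply(pop, function(s) s$outline$total_length_mm, numeric(1))
  # reference mean 24.31 mm; Monte-Carlo of the size distribution keeps
  # the sample mean within 20%
  expect_lt(abs(mean(tl) - 24.31) / 24.31, 0.20)
})

test_that("same module count can come with twofold length differences", {
  pop <- generate_population(500, growth_params(rng_seed = 31,
                                                n_vertices = 256L))
  tl <- vapply(pop, function(s) s$outline$total_length_mm, numeric(1))
  n <- vapply(pop, function(s) s$n_modules_true, integer(1))
  spread <- tapply(tl, n, function(v) max(v) / min(v))
  expect_true(any(spread >= 2, na.rm = TRUE))
})

test_that("parameter invariants are enforced", {
  expect_error(growth_params(width_ratio = 1.2), "width_ratio")
  expect_error(growth_params(mlom_decay_ratio = 1), "mlom_decay_ratio")
  expect_error(growth_params(amu_midline_fraction = 0.6), "amu")
  expect_error(generate_specimen(-3), "total_length")
  expect_error(generate_population(3, dist = list(name = "cauchy")),
               "unsupported")
})
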