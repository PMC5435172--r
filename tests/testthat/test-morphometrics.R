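test_that("length and width are measured along the outline's own axes", {
  o <- build_outline(10, 5, 1024)
  s <- dickinsonia:::new_specimen("bare", o, list(), integer(0), 0L,
                                  which.min(o$points[, 1]))
  expect_equal(measure_total_length(s), 10, tolerance = 1e-3)
  expect_equal(measure_total_width(s), 5, tolerance = 1e-3)

  th <- 0.6
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s_rot <- s
  s_rot$outline$points <- o$points %*% t(rot)
  expect_equal(measure_total_length(s_rot), 10, tolerance = 1e-3)
  expect_equal(measure_total_width(s_rot), 5, tolerance = 1e-3)
})

test_that("midline and margin lengths are straight-line distances", {
  set.seed(51)
  s <- generate_specimen(24.31, noise_free_params())
  n <- s$n_modules_true

  gen_mlm <- s$generation$mlm_lengths
  for (i in seq_len(n)) {
    expect_equal(measure_mlm(s, i, "left"), gen_mlm[i], tolerance = 1e-6)
    expect_equal(measure_mlm(s, i, "left"), measure_mlm(s, i, "right"),
                 tolerance = 1e-9)
  }

  # chord never exceeds the arc of the same margin interval
  pts <- s$outline$points
  for (i in seq_len(n)) {
    iv <- dickinsonia:::margin_interval(s, i, "left")
    arc <- dickinsonia:::arc_between(pts, iv$start_index, iv$end_index)
    expect_lte(measure_mlom(s, i, "left"), arc + 1e-12)
  }
  expect_error(measure_mlm(s, n + 1), "out of range")
  expect_error(measure_mlom(s, 0), "out of range")
})

test_that("module width is the arc length of the medial path", {
  set.seed(52)
  s <- generate_specimen(30, noise_free_params())
  n <- s$n_modules_true
  for (i in c(1L, n %/% 2L, n)) {
    m <- dickinsonia:::module_lookup(s, i, "left")
    chord <- sqrt(sum((m$medial_curve[1, ] -
                         m$medial_curve[nrow(m$medial_curve), ])^2))
    expect_gte(measure_mw(s, i), chord - 1e-12)
  }
  # anterior modules are bent: the medial arc strictly exceeds its chord
  m1 <- dickinsonia:::module_lookup(s, 1L, "left")
  chord1 <- sqrt(sum((m1$medial_curve[1, ] -
                        m1$medial_curve[nrow(m1$medial_curve), ])^2))
  expect_gt(measure_mw(s, 1), chord1)
})

test_that("a semicircular anterior cap measures as pi * r", {
  t <- seq(-pi / 2, 3 * pi / 2, length.out = 4097)[-4097]
  pts <- cbind(5 * cos(t), 5 * sin(t))
  o <- dickinsonia:::new_body_outline(pts, 10, 10, 4096)
  s <- dickinsonia:::new_specimen("cap", o, list(), 1:2049, 0L,
                                  which.min(pts[, 1]))
  expect_equal(measure_amu(s), 5 * pi, tolerance = 1e-4)
})

test_that("the full protocol censors, measures and flags eligibility", {
  set.seed(53)
  s <- generate_specimen(24, noise_free_params())
  rec <- measure_specimen(s, delta = 0)
  expect_identical(rec$n_modules_observed, s$n_modules_true)
  expect_identical(nrow(rec$modules), 2L * s$n_modules_true)
  expect_true(rec$module_stats_eligible)
  expect_gt(rec$amu_margin_mm, 0)

  # censoring consistency with the standalone resolution operation
  delta <- dickinsonia:::mlom_sums_by_module(s)[s$n_modules_true] * 1.01
  rec_c <- measure_specimen(s, delta = delta)
  expect_identical(rec_c$n_modules_observed,
                   apply_resolution_limit(s, delta)$n_modules_observed)
  expect_lt(rec_c$n_modules_observed, s$n_modules_true)

  # a record resolving 70% of its modules is not module-eligible
  delta_70 <- sort(dickinsonia:::mlom_sums_by_module(s),
                   decreasing = TRUE)[ceiling(0.7 * s$n_modules_true)]
  rec_70 <- measure_specimen(s, delta = delta_70 * 1.001)
  expect_lte(rec_70$measurable_fraction, 0.75)
  expect_false(rec_70$module_stats_eligible)
})

test_that("measurement is deterministic", {
  pop <- generate_population(5, growth_params(rng_seed = 2,
                                              n_vertices = 256L))
  r1 <- measure_population(pop, delta = 0.5)
  r2 <- measure_population(pop, delta = 0.5)
  expect_identical(r1, r2)
})
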