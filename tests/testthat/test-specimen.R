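test_that("freshly simulated specimens satisfy every geometric invariant", {
  set.seed(11)
  p <- growth_params(n_vertices = 1024L)
  for (tl in c(4.2, 24.31, 90)) {
    s <- generate_specimen(tl, p)
    expect_identical(validate_specimen(s), character(0))
  }
})

test_that("validation names injected defects", {
  set.seed(12)
  s <- generate_specimen(24, noise_free_params())

  # swap the margin anchors of two adjacent left boundary curves so the
  # curves cross
  b2 <- s$modules[[2]]$boundary_curve
  b3 <- s$modules[[3]]$boundary_curve
  s_bad <- s
  s_bad$modules[[2]]$boundary_curve <-
    rbind(b2[1:(nrow(b2) - 1), ], b3[nrow(b3), ])
  s_bad$modules[[3]]$boundary_curve <-
    rbind(b3[1:(nrow(b3) - 1), ], b2[nrow(b2), ])
  v <- validate_specimen(s_bad)
  expect_true(any(grepl("cross", v)))

  # delete left module 3: count asymmetry
  s_asym <- s
  s_asym$modules <- s_asym$modules[-3]
  v2 <- validate_specimen(s_asym)
  expect_true(any(grepl("count asymmetry", v2)))
})

test_that("specimens are mirror-symmetric about the long axis", {
  set.seed(13)
  s <- generate_specimen(30, noise_free_params())
  m <- dickinsonia:::mirror_specimen(s)
  for (i in seq_len(s$n_modules_true)) {
    for (side in c("left", "right")) {
      expect_equal(measure_mlm(m, i, side), measure_mlm(s, i, side),
                   tolerance = 1e-9)
      expect_equal(measure_mlom(m, i, side),
                   measure_mlom(s, i,
                                if (side == "left") "right" else "left"),
                   tolerance = 1e-9)
      expect_equal(measure_mw(m, i, side),
                   measure_mw(s, i,
                              if (side == "left") "right" else "left"),
                   tolerance = 1e-9)
    }
  }
})

test_that("AMU arc and module margin arcs partition the perimeter", {
  set.seed(14)
  p <- growth_params(n_vertices = 1024L)
  for (rep in 1:5) {
    s <- generate_specimen(stats::runif(1, 5, 80), p)
    pts <- s$outline$points
    per <- dickinsonia:::closed_perimeter(pts)
    amu_arc <- polyline_arc_length(pts[s$amu$arc_point_indices, ])
    mod_arc <- 0
    for (side in c("left", "right")) {
      for (i in seq_len(s$n_modules_true)) {
        iv <- dickinsonia:::margin_interval(s, i, side)
        mod_arc <- mod_arc +
          dickinsonia:::arc_between(pts, iv$start_index, iv$end_index)
      }
    }
    expect_equal(amu_arc + mod_arc, per, tolerance = 0.005)
  }
})
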