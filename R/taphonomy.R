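#' Taphonomic degradation parameters
#'
#' Controls how ideal specimens are degraded into fossil-like
#' observations: a grain-size resolution limit below which posterior
#' modules cannot be resolved (so observed module counts are minimum
#' estimates), a smooth soft-body distortion field, a small midline shear
#' emulating apparent module offset, and a completeness probability.
#'
#' @param resolution_mm Grain-size limit delta (mm, >= 0): a module is
#'   unresolvable when its summed left+right outer-margin length falls
#'   below it. Default 0.5 mm, an order-of-magnitude choice for
#'   medium-grained sandstone casts.
#' @param distortion_sigma RMS magnitude (mm) of the smooth random
#'   displacement field (0 disables).
#' @param asymmetry_shear Shear coefficient applied as x' = x + shear * y.
#' @param completeness Probability that a specimen survives complete and
#'   measurable.
#' @param rng_seed Optional seed for the distortion field and the
#'   completeness draw.
#' @return A `taphonomy_params` list.
#' @export
taphonomy_params <- function(resolution_mm = 0.5, distortion_sigma = 0,
                             asymmetry_shear = 0, completeness = 1,
                             rng_seed = NULL) {
  stopifnot_msg(resolution_mm >= 0, "resolution_mm must be >= 0")
  stopifnot_msg(distortion_sigma >= 0, "distortion_sigma must be >= 0")
  stopifnot_msg(completeness >= 0 && completeness <= 1,
                "completeness must be in [0, 1]")
  structure(list(resolution_mm = resolution_mm,
                 distortion_sigma = distortion_sigma,
                 asymmetry_shear = asymmetry_shear,
                 completeness = completeness, rng_seed = rng_seed),
            class = "taphonomy_params")
}

# Observed module count after posterior censoring: strip contiguous
# posterior modules whose summed left+right outer-margin length is below
# delta. Interior modules are never removed (resolution loss is a
# posterior phenomenon: the newest modules are the smallest).
censored_module_count <- function(mlom_sums, delta) {
  n <- length(mlom_sums)
  if (delta <= 0) return(n)
  while (n >= 1L && mlom_sums[n] < delta) n <- n - 1L
  n
}

# Summed left+right outer-margin chord per module, anterior -> posterior.
mlom_sums_by_module <- function(s) {
  vapply(seq_len(s$n_modules_true), function(i) {
    measure_mlom(s, i, "left") + measure_mlom(s, i, "right")
  }, numeric(1))
}

#' Apply the grain-size resolution limit
#'
#' Posterior modules whose summed left+right outer-margin length is below
#' `delta` are merged into an unresolved posterior mass; the observed
#' module count (a minimum estimate of the true count) is recorded on the
#' specimen. `delta = 0` leaves the specimen fully resolved.
#'
#' @param s A `specimen`.
#' @param delta Resolution limit in mm (>= 0).
#' @return The specimen with `n_modules_observed` set; if no module is
#'   resolvable the specimen is flagged `unmeasurable`.
#' @export
apply_resolution_limit <- function(s, delta) {
  stopifnot_msg(delta >= 0, "delta must be >= 0")
  n_obs <- if (s$n_modules_true > 0L) {
    censored_module_count(mlom_sums_by_module(s), delta)
  } else 0L
  s$n_modules_observed <- as.integer(n_obs)
  s$unmeasurable <- n_obs == 0L
  s
}

#' Apply soft-body distortion
#'
#' Displaces every stored coordinate (outline, anchors, boundary and
#' medial curves) by a smooth low-order random field plus an optional
#' shear. A few random harmonics over the body, rather than white noise,
#' mimic soft-body deformation as opposed to digitization jitter. With
#' zero magnitudes the specimen is returned bit-identical.
#'
#' @param s A `specimen`.
#' @param params A [taphonomy_params()]; `distortion_sigma` (mm) sets the
#'   RMS displacement over the outline, `asymmetry_shear` the shear.
#' @return The distorted specimen, flagged as such.
#' @export
apply_distortion <- function(s, params = taphonomy_params()) {
  sigma <- params$distortion_sigma
  shear <- params$asymmetry_shear
  if (sigma == 0 && shear == 0) return(s)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  tl <- s$outline$total_length_mm

  k <- 4L
  amp <- matrix(stats::rnorm(2L * k), k, 2L)
  freq <- matrix(stats::runif(2L * k, 0.5, 1.8), k, 2L)
  phase <- matrix(stats::runif(2L * k, 0, 2 * pi), k, 2L)
  raw_field <- function(pts) {
    u <- pts[, 1L] / tl
    v <- pts[, 2L] / tl
    dx <- numeric(nrow(pts))
    dy <- numeric(nrow(pts))
    for (j in seq_len(k)) {
      dx <- dx + amp[j, 1L] *
        sin(2 * pi * (freq[j, 1L] * u + freq[j, 2L] * v) + phase[j, 1L])
      dy <- dy + amp[j, 2L] *
        sin(2 * pi * (freq[j, 2L] * u - freq[j, 1L] * v) + phase[j, 2L])
    }
    cbind(dx, dy, deparse.level = 0L)
  }
  base <- raw_field(s$outline$points)
  rms <- sqrt(mean(base[, 1L]^2 + base[, 2L]^2))
  scale <- if (rms > 0) sigma / rms else 0

  warp <- function(pts) {
    one_row <- is.null(dim(pts))
    if (one_row) pts <- matrix(pts, 1L, 2L)
    out <- pts + scale * raw_field(pts)
    out[, 1L] <- out[, 1L] + shear * out[, 2L]
    if (one_row) out[1L, ] else out
  }

  s$outline$points <- warp(s$outline$points)
  s$modules <- lapply(s$modules, function(m) {
    m$midline_anchor <- warp(m$midline_anchor)
    m$margin_anchor <- warp(m$margin_anchor)
    m$boundary_curve <- warp(m$boundary_curve)
    m$medial_curve <- warp(m$medial_curve)
    m
  })
  s$generation$distorted <- TRUE
  s$provenance <- paste0(sub("-distorted$", "", s$provenance), "-distorted")
  s
}

#' Completeness filter for a population
#'
#' Retains each specimen independently with probability
#' `params$completeness` (seeded Bernoulli), emulating the selection of
#' complete, undeformed specimens from a larger examined sample.
#'
#' @param pop List of `specimen` objects.
#' @param params A [taphonomy_params()].
#' @return List with elements `complete` and `excluded` (each a list of
#'   specimens); excluded specimens carry an `exclusion_reason`.
#' @export
apply_completeness_filter <- function(pop, params = taphonomy_params()) {
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  keep <- stats::runif(length(pop)) < params$completeness
  excluded <- lapply(pop[!keep], function(s) {
    s$exclusion_reason <- "incomplete or deformed"
    s
  })
  list(complete = pop[keep], excluded = excluded)
}
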