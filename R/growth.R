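#' Growth-model parameters
#'
#' Parameters of the developmental model: isometric outline growth with a
#' fixed width-to-length ratio, sublinear module-number scaling, uniform
#' module length at the midline, and a posterior-ward geometric decay of
#' outer-margin arc allocations (anterior modules claim more of the
#' margin, which is what the adjacent-module increase statistic detects).
#'
#' Defaults are calibration choices, not measured facts: `width_ratio`
#' 0.8663 is the ratio of the mean width and mean length of the reference
#' population (21.06 / 24.31 mm); `mlom_decay_ratio` 0.96 makes the
#' expected adjacent-module increase statistic 100 * (1 - r) = 4%;
#' `module_count_coeff` / `module_count_exponent` give a sublinear
#' (square-root) module-number law, and `module_count_dispersion` 0.12 is
#' set so the population-level module-number fits land near the reference
#' coefficients of determination (about 0.85 on the log-log scale) while
#' same-module-count specimens still differ in length by a factor of two.
#'
#' @param width_ratio Mean TW/TL ratio (0 < c <= 1).
#' @param width_noise_cv Lognormal coefficient of variation of TW about
#'   `width_ratio * TL` (0 disables noise).
#' @param amu_midline_fraction Fraction of TL occupied by the anterior-most
#'   unit along the midline (0 < f < 0.5).
#' @param module_count_coeff,module_count_exponent Module-number scaling
#'   N ~ coeff * TL^exponent (coeff > 0, 0 < exponent <= 1).
#' @param module_count_dispersion Lognormal sd of the module count about
#'   the scaling law.
#' @param mlom_decay_ratio Posterior-ward geometric ratio r of margin arc
#'   allocations (0 < r < 1).
#' @param margin_noise_cv Optional lognormal jitter on per-module margin
#'   allocations (default 0: off).
#' @param shape_blend_exponent Exponent mapping normalized anterior
#'   position to the "v"-to-"u" boundary bending weight (1 = linear).
#' @param growth_rate Per-step relative length increment g for growth
#'   trajectories.
#' @param n_vertices Outline polyline resolution.
#' @param rng_seed Optional integer seed; populations are bit-reproducible
#'   under it.
#' @return A `growth_params` list.
#' @export
growth_params <- function(width_ratio = 0.8663,
                          width_noise_cv = 0.05,
                          amu_midline_fraction = 0.12,
                          module_count_coeff = 3.0,
                          module_count_exponent = 0.5,
                          module_count_dispersion = 0.12,
                          mlom_decay_ratio = 0.96,
                          margin_noise_cv = 0,
                          shape_blend_exponent = 1,
                          growth_rate = 0.1,
                          n_vertices = 2048L,
                          rng_seed = NULL) {
  p <- list(width_ratio = width_ratio, width_noise_cv = width_noise_cv,
            amu_midline_fraction = amu_midline_fraction,
            module_count_coeff = module_count_coeff,
            module_count_exponent = module_count_exponent,
            module_count_dispersion = module_count_dispersion,
            mlom_decay_ratio = mlom_decay_ratio,
            margin_noise_cv = margin_noise_cv,
            shape_blend_exponent = shape_blend_exponent,
            growth_rate = growth_rate,
            n_vertices = as.integer(n_vertices), rng_seed = rng_seed)
  validate_growth_params(p)
  structure(p, class = "growth_params")
}

validate_growth_params <- function(p) {
  stopifnot_msg(p$width_ratio > 0 && p$width_ratio <= 1,
                "width_ratio must be in (0, 1]")
  stopifnot_msg(p$mlom_decay_ratio > 0 && p$mlom_decay_ratio < 1,
                "mlom_decay_ratio must be in (0, 1)")
  stopifnot_msg(p$amu_midline_fraction > 0 && p$amu_midline_fraction < 0.5,
                "amu_midline_fraction must be in (0, 0.5)")
  stopifnot_msg(p$module_count_coeff > 0, "module_count_coeff must be > 0")
  stopifnot_msg(p$module_count_exponent > 0 && p$module_count_exponent <= 1,
                "module_count_exponent must be in (0, 1]")
  stopifnot_msg(p$width_noise_cv >= 0 && p$module_count_dispersion >= 0 &&
                  p$margin_noise_cv >= 0, "noise levels must be >= 0")
  stopifnot_msg(p$growth_rate > 0, "growth_rate must be > 0")
  invisible(p)
}

stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Partition the modular margin into geometrically decaying allocations
#'
#' Outer-margin arc allocations are proportional to `r^(i - 1)` from the
#' anterior (i = 1) to the posterior, normalized to the available modular
#' perimeter, so that consecutive allocations have the exact ratio `r`:
#' anterior modules claim more of the margin.
#'
#' @param perimeter_modular Total arc length (mm) to distribute (one side,
#'   cap edge to posterior pole).
#' @param n_modules Number of modules (>= 1).
#' @param r Geometric ratio in (0, 1).
#' @return Numeric vector of `n_modules` strictly decreasing arc lengths
#'   summing to `perimeter_modular`.
#' @examples
#' allocate_margin(100, 2, 0.5)  # 66.67, 33.33
#' @export
allocate_margin <- function(perimeter_modular, n_modules, r) {
  stopifnot_msg(r > 0 && r < 1, "r must be in (0, 1)")
  stopifnot_msg(n_modules >= 1, "n_modules must be >= 1")
  stopifnot_msg(perimeter_modular > 0, "perimeter_modular must be > 0")
  w <- r^(seq_len(n_modules) - 1)
  perimeter_modular * w / sum(w)
}

# Shared geometric constructor. Places midline anchors from explicit
# per-module midline lengths (anterior -> posterior, summing to the
# modular midline interval), margin anchors from explicit per-module
# weights (normalized per side), and builds boundary and medial curves by
# a quadratic Bezier whose control point blends between the chord
# midpoint ("v", straight) and the corner (x_midline, y_margin)
# ("u": perpendicular at the midline, parallel to the long axis at the
# outer end), weighted by normalized anterior position.
build_specimen_geometry <- function(total_length, total_width,
                                    mlm_lengths, margin_weights,
                                    amu_fraction, n_vertices,
                                    blend_exponent = 1,
                                    specimen_id = "sim",
                                    provenance = "simulated",
                                    rng_seed_used = NA_integer_,
                                    decay_ratio = NA_real_,
                                    curve_points = 33L) {
  check_dimensions(total_length, total_width)
  a <- total_length / 2
  b <- total_width / 2
  n_mod <- length(mlm_lengths)
  stopifnot_msg(n_mod >= 1 && n_mod == length(margin_weights),
                "mlm_lengths and margin_weights must have equal length >= 1")
  x_amu <- a - amu_fraction * total_length
  t_c <- acos(min(1, max(-1, x_amu / a)))

  # upper (left, y >= 0) half: uniform parametric angles plus the cap edge
  nv <- max(64L, as.integer(n_vertices))
  tt <- sort(unique(c(seq(0, pi, length.out = nv %/% 2L + 1L), pi / 2, t_c)))
  up <- cbind(a * cos(tt), b * sin(tt))
  cum <- cum_arc_length(up)
  s_c <- cum[match(t_c, tt)]
  arc_side <- cum[length(cum)] - s_c

  lens <- arc_side * margin_weights / sum(margin_weights)
  s_anchor <- s_c + cumsum(lens)           # arc positions of anchors 1..N
  t_anchor <- stats::approx(cum, tt, xout = s_anchor, rule = 2)$y
  t_anchor[n_mod] <- pi                    # posterior pole, exactly
  tA <- c(t_c, t_anchor)                   # anchors 0..N (0 = cap edge)

  tu <- sort(unique(c(tt, tA)))
  # full outline, counterclockwise, starting at the right cap edge (-t_c)
  neg_ant <- -rev(tu[tu > 0 & tu < t_c])
  neg_post <- -rev(tu[tu > t_c & tu < pi])
  t_full <- c(-t_c, neg_ant, tu, neg_post)
  pts <- cbind(a * cos(t_full), b * sin(t_full))

  offset <- 1L + length(neg_ant)
  idx_upper <- function(t) offset + match(t, tu)
  idx_left <- vapply(tA, idx_upper, numeric(1))          # anchors 0..N
  pole_idx <- idx_upper(pi)
  idx_right <- c(1L, rep(NA_integer_, n_mod))
  if (n_mod >= 2L) {
    for (j in seq_len(n_mod - 1L)) {
      idx_right[j + 1L] <- pole_idx + match(-tA[j + 1L], neg_post)
    }
  }
  idx_right[n_mod + 1L] <- pole_idx
  amu_indices <- 1:idx_left[1L]

  # midline anchors x_0 .. x_{N-1} (anterior edge of each module)
  l_mod <- x_amu + a
  scale_mlm <- l_mod / sum(mlm_lengths)
  x_bound <- x_amu - c(0, cumsum(mlm_lengths * scale_mlm))
  x_bound[n_mod + 1L] <- -a

  bez_boundary <- function(m, e, beta) {
    p1 <- (1 - beta) * (m + e) / 2 + beta * c(m[1L], e[2L])
    quadratic_bezier(m, p1, e, curve_points)
  }
  # + 0 turns IEEE -0 into +0 so mirrored curves serialize identically
  flip <- function(cu) { cu[, 2L] <- -cu[, 2L] + 0; cu }

  s_edges <- c(s_c, s_anchor)
  modules <- vector("list", 2L * n_mod)
  for (i in seq_len(n_mod)) {
    xa <- x_bound[i]
    srel <- (xa + a) / l_mod
    beta <- srel^blend_exponent
    m_pt <- c(xa, 0)
    e_left <- pts[idx_left[i], ]
    b_left <- bez_boundary(m_pt, e_left, beta)

    mm_x <- (x_bound[i] + x_bound[i + 1L]) / 2
    srel_m <- (mm_x + a) / l_mod
    beta_m <- max(0, srel_m)^blend_exponent
    sm <- (s_edges[i] + s_edges[i + 1L]) / 2
    tm <- stats::approx(cum, tt, xout = sm, rule = 2)$y
    em_left <- c(a * cos(tm), b * sin(tm))
    med_left <- bez_boundary(c(mm_x, 0), em_left, beta_m)

    modules[[i]] <- new_module_geometry(
      i, "left", m_pt, e_left, b_left, med_left,
      idx_left[i], idx_left[i + 1L])
    modules[[n_mod + i]] <- new_module_geometry(
      i, "right", m_pt, pts[idx_right[i], ], flip(b_left), flip(med_left),
      idx_right[i + 1L], idx_right[i])
  }

  outline <- new_body_outline(pts, total_length, total_width, nv)
  new_specimen(
    specimen_id, outline, modules, amu_indices, n_mod, pole_idx,
    provenance = provenance, rng_seed_used = rng_seed_used,
    generation = list(
      width_ratio = total_width / total_length,
      decay_ratio = decay_ratio, amu_midline_fraction = amu_fraction,
      mlm_lengths = mlm_lengths * scale_mlm, margin_lengths = lens,
      blend_exponent = blend_exponent, x_amu = x_amu, distorted = FALSE))
}

#' Generate one synthetic specimen
#'
#' Draws total width and module count from the growth model, then builds
#' the full 2-D geometry: uniform module lengths at the midline with the
#' anterior-most unit occupying the anterior midline fraction, margin
#' anchors placed so consecutive outer-margin arc allocations form a
#' geometric series with ratio `mlom_decay_ratio` posterior-ward, and
#' boundary curves blending from straight ("v") at the posterior to bent
#' ("u") at the anterior.
#'
#' @param total_length TL in mm (> 0).
#' @param params A [growth_params()] object.
#' @param specimen_id Identifier stored in the specimen.
#' @return A `specimen`; always passes [validate_specimen()].
#' @export
generate_specimen <- function(total_length, params = growth_params(),
                              specimen_id = "sim-1") {
  validate_growth_params(params)
  stopifnot_msg(total_length > 0, "total_length must be > 0")
  seed_used <- NA_integer_
  if (!is.null(params$rng_seed)) {
    set.seed(params$rng_seed)
    seed_used <- as.integer(params$rng_seed)
  }
  tw <- params$width_ratio * total_length *
    exp(stats::rnorm(1, 0, params$width_noise_cv))
  tw <- min(tw, total_length)  # truncate: width never exceeds length
  n <- max(3L, as.integer(round(
    params$module_count_coeff * total_length^params$module_count_exponent *
      exp(stats::rnorm(1, 0, params$module_count_dispersion)))))
  w <- params$mlom_decay_ratio^(seq_len(n) - 1)
  if (params$margin_noise_cv > 0) {
    w <- w * exp(stats::rnorm(n, 0, params$margin_noise_cv))
  }
  build_specimen_geometry(
    total_length, tw, mlm_lengths = rep(1, n), margin_weights = w,
    amu_fraction = params$amu_midline_fraction,
    n_vertices = params$n_vertices,
    blend_exponent = params$shape_blend_exponent,
    specimen_id = specimen_id, rng_seed_used = seed_used,
    decay_ratio = params$mlom_decay_ratio)
}

#' Simulate a growth trajectory with posterior terminal addition
#'
#' Total length grows geometrically by `growth_rate` per step; the target
#' module count follows the scaling law; a new module is inserted at the
#' posterior whenever the modular midline interval exceeds
#' (N + 1/2) x MLM, and a newly inserted module ramps its midline length
#' (and its margin allocation) up to match the others before the next
#' insertion. Module identity is anterior-indexed, so index i refers to
#' the same module in every snapshot.
#'
#' @param initial_length Starting TL (mm).
#' @param n_steps Number of growth increments (>= 1); the trajectory
#'   contains `n_steps + 1` snapshots including the initial state.
#' @param params A [growth_params()] object. Width and count noise are
#'   drawn once per trajectory so snapshots stay internally consistent.
#' @return List of `growth_snapshot` objects with fields `step`,
#'   `specimen`, `total_length_mm`, `n_modules_true`, `mlm_mm`.
#' @export
simulate_growth_trajectory <- function(initial_length, n_steps,
                                       params = growth_params()) {
  validate_growth_params(params)
  stopifnot_msg(initial_length > 0, "initial_length must be > 0")
  stopifnot_msg(n_steps >= 1, "n_steps must be >= 1")
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  width_factor <- exp(stats::rnorm(1, 0, params$width_noise_cv))
  count_factor <- exp(stats::rnorm(1, 0, params$module_count_dispersion))
  f <- params$amu_midline_fraction
  r <- params$mlom_decay_ratio

  tl0 <- initial_length
  n_target0 <- params$module_count_coeff * tl0^params$module_count_exponent *
    count_factor
  n <- max(3L, as.integer(round(n_target0)))

  snapshots <- vector("list", n_steps + 1L)
  for (step in 0:n_steps) {
    tl <- tl0 * (1 + params$growth_rate)^step
    tw <- min(tl, params$width_ratio * tl * width_factor)
    n_target <- params$module_count_coeff * tl^params$module_count_exponent *
      count_factor
    l_mod <- tl * (1 - f)
    mlm <- l_mod / n_target
    while (l_mod > (n + 0.5) * mlm) n <- n + 1L
    last_len <- l_mod - (n - 1L) * mlm
    mlm_lengths <- c(rep(mlm, n - 1L), last_len)
    ramp <- min(1, max(last_len / mlm - 0.5, 1e-6))
    weights <- r^(seq_len(n) - 1)
    weights[n] <- weights[n] * ramp
    sp <- build_specimen_geometry(
      tl, tw, mlm_lengths, weights, f, params$n_vertices,
      blend_exponent = params$shape_blend_exponent,
      specimen_id = sprintf("traj-step-%03d", step),
      decay_ratio = r)
    snapshots[[step + 1L]] <- structure(
      list(step = step, specimen = sp, total_length_mm = tl,
           n_modules_true = n, mlm_mm = mlm),
      class = "growth_snapshot")
  }
  snapshots
}

#' Specimen size distributions
#'
#' @param name One of `"lognormal"` (args `meanlog`, `sdlog`),
#'   `"uniform"` (args `min`, `max`) or `"fixed"` (arg `value`). The
#'   default lognormal has mean 24.31 mm and spans roughly 4-120 mm over
#'   its central 99.8%.
#' @param ... Distribution arguments overriding the defaults.
#' @return A `size_distribution` specification.
#' @export
size_distribution <- function(name = "lognormal", ...) {
  args <- list(...)
  defaults <- switch(
    name,
    lognormal = list(meanlog = log(24.31) - 0.55^2 / 2, sdlog = 0.55),
    uniform = list(min = 4, max = 140),
    fixed = list(value = 24.31),
    stop(sprintf("unsupported size distribution '%s'", name), call. = FALSE))
  spec <- utils::modifyList(defaults, args)
  structure(c(list(name = name), spec), class = "size_distribution")
}

draw_sizes <- function(n, dist) {
  switch(
    dist$name,
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    uniform = stats::runif(n, dist$min, dist$max),
    fixed = rep(dist$value, n),
    stop(sprintf("unsupported size distribution '%s'", dist$name),
         call. = FALSE))
}

#' Generate a synthetic population
#'
#' Draws specimen sizes from `dist` and generates one specimen per size.
#' A single master seed (`params$rng_seed`) drives both the size draws
#' and deterministically derived per-specimen seeds, so the population is
#' bit-reproducible.
#'
#' @param n_specimens Number of specimens (>= 1).
#' @param params A [growth_params()] object; set `rng_seed` for
#'   reproducibility.
#' @param dist A [size_distribution()].
#' @return List of `specimen` objects.
#' @export
generate_population <- function(n_specimens, params = growth_params(),
                                dist = size_distribution()) {
  validate_growth_params(params)
  stopifnot_msg(n_specimens >= 1, "n_specimens must be >= 1")
  if (!inherits(dist, "size_distribution")) {
    dist <- do.call(size_distribution, as.list(dist))
  }
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  sizes <- draw_sizes(n_specimens, dist)
  seeds <- sample.int(.Machine$integer.max - 1L, n_specimens)
  sub <- params
  sub$rng_seed <- NULL
  lapply(seq_len(n_specimens), function(i) {
    set.seed(seeds[i])
    s <- generate_specimen(sizes[i], sub,
                           specimen_id = sprintf("sim-%04d", i))
    s$rng_seed_used <- seeds[i]
    s
  })
}
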