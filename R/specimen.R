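#' Build an elliptical body outline
#'
#' The body of *Dickinsonia costata* is ovoid: the outline is modelled as a
#' true ellipse with semi-axes `total_length / 2` (long, anterior-posterior,
#' x) and `total_width / 2` (short, y), discretized at uniformly spaced
#' parametric angles. The polyline always contains the four cardinal
#' vertices so that its bounding box reproduces the nominal dimensions.
#'
#' Coordinate frame: long axis = x, anterior at +x, posterior at -x,
#' origin at the centroid; units mm throughout.
#'
#' @param total_length Long-axis extent (TL, mm).
#' @param total_width Short-axis extent (TW, mm); must not exceed
#'   `total_length`.
#' @param n_vertices Resolution of the polyline (>= 64).
#' @return A `body_outline`: list with `total_length_mm`, `total_width_mm`,
#'   `points` (n x 2 matrix, closed by convention, no repeated vertex) and
#'   `n_vertices`.
#' @examples
#' o <- build_outline(10, 5, 512)
#' closed <- rbind(o$points, o$points[1, ])
#' polyline_arc_length(closed)  # perimeter
#' @export
build_outline <- function(total_length, total_width, n_vertices = 2048L) {
  check_dimensions(total_length, total_width)
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 64L) {
    stop("n_vertices must be at least 64", call. = FALSE)
  }
  t <- sort(unique(c(2 * pi * (0:(n_vertices - 1L)) / n_vertices,
                     pi / 2, pi, 3 * pi / 2)))
  pts <- cbind(total_length / 2 * cos(t), total_width / 2 * sin(t))
  new_body_outline(pts, total_length, total_width, n_vertices)
}

new_body_outline <- function(points, total_length, total_width, n_vertices) {
  structure(
    list(total_length_mm = total_length, total_width_mm = total_width,
         points = points, n_vertices = as.integer(n_vertices)),
    class = "body_outline"
  )
}

check_dimensions <- function(total_length, total_width) {
  if (!is.finite(total_length) || total_length <= 0 ||
      !is.finite(total_width) || total_width <= 0) {
    stop("total_length and total_width must be positive", call. = FALSE)
  }
  if (total_width > total_length) {
    stop("total_width must not exceed total_length (long axis is ",
         "anterior-posterior)", call. = FALSE)
  }
  invisible(TRUE)
}

new_module_geometry <- function(index, side, midline_anchor, margin_anchor,
                                boundary_curve, medial_curve,
                                margin_start_index, margin_end_index) {
  structure(
    list(index = as.integer(index), side = side,
         midline_anchor = midline_anchor, margin_anchor = margin_anchor,
         boundary_curve = boundary_curve, medial_curve = medial_curve,
         margin_start_index = as.integer(margin_start_index),
         margin_end_index = as.integer(margin_end_index)),
    class = "module_geometry"
  )
}

new_specimen <- function(specimen_id, outline, modules, amu_indices,
                         n_modules_true, posterior_pole_index,
                         provenance = "simulated", rng_seed_used = NA_integer_,
                         generation = list()) {
  structure(
    list(specimen_id = specimen_id, outline = outline, modules = modules,
         amu = list(arc_point_indices = as.integer(amu_indices)),
         n_modules_true = as.integer(n_modules_true),
         n_modules_observed = as.integer(n_modules_true),
         posterior_pole_index = as.integer(posterior_pole_index),
         provenance = provenance, rng_seed_used = rng_seed_used,
         generation = generation),
    class = "specimen"
  )
}

#' @export
print.specimen <- function(x, ...) {
  cat(sprintf(
    "<specimen %s> TL %.2f mm, TW %.2f mm, %d modules/side (%s)\n",
    x$specimen_id, x$outline$total_length_mm, x$outline$total_width_mm,
    x$n_modules_true, x$provenance))
  invisible(x)
}

# Find one module by index and side ("left"/"right"). Fast path exploits
# the canonical storage order (all left modules, then all right modules);
# falls back to a scan for specimens assembled differently.
module_lookup <- function(s, index, side) {
  n <- s$n_modules_true
  pos <- if (side == "left") index else n + index
  if (pos >= 1L && pos <= length(s$modules)) {
    m <- s$modules[[pos]]
    if (m$index == index && m$side == side) return(m)
  }
  for (m in s$modules) {
    if (m$index == index && m$side == side) return(m)
  }
  stop(sprintf("module index %d (%s) not present in specimen '%s'",
               index, side, s$specimen_id), call. = FALSE)
}

modules_on_side <- function(s, side) {
  mods <- Filter(function(m) m$side == side, s$modules)
  mods[order(vapply(mods, function(m) m$index, integer(1)))]
}

# Margin anchors bounding module `index` on one side: the module's own
# (anterior) anchor and the next module's anchor, or the posterior pole
# for the last module.
margin_interval <- function(s, index, side) {
  m <- module_lookup(s, index, side)
  post_anchor <- if (index < s$n_modules_true) {
    module_lookup(s, index + 1L, side)$margin_anchor
  } else {
    s$outline$points[s$posterior_pole_index, ]
  }
  list(anterior = m$margin_anchor, posterior = post_anchor,
       start_index = m$margin_start_index, end_index = m$margin_end_index)
}

#' Validate a specimen's geometric invariants
#'
#' Checks the structural contract every specimen must satisfy: positive
#' ovoid dimensions, bounding box consistent with the nominal dimensions,
#' equal left/right module counts, mirror symmetry for undistorted
#' simulated specimens, boundary curves anchored on the midline and
#' outline, non-crossing adjacent boundary curves, posterior midline
#' anchor at the posterior pole, and arc-length closure (AMU arc plus all
#' module margin arcs account for the whole perimeter).
#'
#' Violations are reported, never raised, so degraded fossils can be
#' inspected rather than rejected.
#'
#' @param s A `specimen`.
#' @return Character vector of violation messages; empty if all hold.
#' @export
validate_specimen <- function(s) {
  v <- character()
  o <- s$outline
  pts <- o$points
  if (!(o$total_length_mm > 0) || !(o$total_width_mm > 0) ||
      o$total_width_mm > o$total_length_mm) {
    v <- c(v, "dimensions: need TL > 0, TW > 0, TW <= TL")
  }
  bb_l <- diff(range(pts[, 1L])); bb_w <- diff(range(pts[, 2L]))
  distorted <- isTRUE(s$generation$distorted)
  if (!distorted) {
    if (abs(bb_l - o$total_length_mm) > 1e-3 * o$total_length_mm ||
        abs(bb_w - o$total_width_mm) > 1e-3 * o$total_width_mm) {
      v <- c(v, "bounding box: outline extents do not reproduce TL/TW to 0.1%")
    }
  }

  left <- modules_on_side(s, "left"); right <- modules_on_side(s, "right")
  if (length(left) != s$n_modules_true || length(right) != s$n_modules_true) {
    v <- c(v, sprintf(
      "module count asymmetry: %d left, %d right, n_modules_true = %d",
      length(left), length(right), s$n_modules_true))
  }
  n_pair <- min(length(left), length(right))

  if (s$provenance == "simulated" && !distorted && n_pair > 0) {
    for (i in seq_len(n_pair)) {
      bl <- left[[i]]$boundary_curve
      br <- right[[i]]$boundary_curve
      if (nrow(bl) == nrow(br)) {
        err <- max(abs(bl[, 1L] - br[, 1L]), abs(bl[, 2L] + br[, 2L]))
        if (err > 1e-9) {
          v <- c(v, sprintf("mirror symmetry: module %d left/right differ by %.3g",
                            left[[i]]$index, err))
        }
      } else {
        v <- c(v, sprintf("mirror symmetry: module %d curves differ in length",
                          left[[i]]$index))
      }
    }
  }

  half_w <- max(abs(pts[, 2L]))
  for (side_mods in list(left, right)) {
    for (m in side_mods) {
      if (abs(m$boundary_curve[1L, 2L]) > 1e-6 * max(1, half_w) + 1e-9) {
        v <- c(v, sprintf("boundary start off midline: module %d (%s)",
                          m$index, m$side))
      }
      endp <- m$boundary_curve[nrow(m$boundary_curve), ]
      if (sqrt(sum((endp - m$margin_anchor)^2)) >
          1e-6 * o$total_length_mm + 1e-9) {
        v <- c(v, sprintf("boundary end off outline anchor: module %d (%s)",
                          m$index, m$side))
      }
    }
    n_side <- length(side_mods)
    if (n_side >= 2L) {
      for (i in seq_len(n_side - 1L)) {
        if (polylines_cross(side_mods[[i]]$boundary_curve,
                            side_mods[[i + 1L]]$boundary_curve)) {
          v <- c(v, sprintf("boundary curves cross: modules %d and %d (%s)",
                            side_mods[[i]]$index, side_mods[[i + 1L]]$index,
                            side_mods[[i]]$side))
        }
      }
    }
  }

  if (length(left) > 0 && !distorted) {
    # the posterior-most midline interval must terminate at the pole
    pole <- pts[s$posterior_pole_index, ]
    if (abs(pole[1L] + o$total_length_mm / 2) > 1e-6 * o$total_length_mm ||
        abs(pole[2L]) > 1e-6 * o$total_length_mm) {
      v <- c(v, "posterior pole vertex is not at (-TL/2, 0)")
    }
    x_min <- min(vapply(c(left, right),
                        function(m) m$midline_anchor[1L], numeric(1)))
    if (x_min <= pole[1L]) {
      v <- c(v, "midline anchors extend past the posterior pole")
    }
  }

  # Arc closure: AMU arc + all module margin arcs partition the perimeter.
  if (length(s$amu$arc_point_indices) >= 2L && n_pair == s$n_modules_true &&
      length(left) == length(right)) {
    per <- closed_perimeter(pts)
    amu_arc <- polyline_arc_length(pts[s$amu$arc_point_indices, , drop = FALSE])
    mod_arc <- 0
    ok <- TRUE
    for (side in c("left", "right")) {
      for (i in seq_len(s$n_modules_true)) {
        iv <- tryCatch(margin_interval(s, i, side), error = function(e) NULL)
        if (is.null(iv)) { ok <- FALSE; break }
        mod_arc <- mod_arc + arc_between(pts, iv$start_index, iv$end_index)
      }
    }
    if (ok && abs(amu_arc + mod_arc - per) > 0.005 * per) {
      v <- c(v, sprintf(
        "arc closure: AMU + module margins = %.6g but perimeter = %.6g",
        amu_arc + mod_arc, per))
    }
  }
  v
}

# Mirror a specimen about the long axis (y -> -y, sides swapped).
# Used by symmetry property tests.
mirror_specimen <- function(s) {
  flip <- function(pts) { pts[, 2L] <- -pts[, 2L] + 0; pts }
  s$outline$points <- flip(s$outline$points)
  s$modules <- lapply(s$modules, function(m) {
    m$side <- if (m$side == "left") "right" else "left"
    m$midline_anchor[2L] <- -m$midline_anchor[2L] + 0
    m$margin_anchor[2L] <- -m$margin_anchor[2L] + 0
    m$boundary_curve <- flip(m$boundary_curve)
    m$medial_curve <- flip(m$medial_curve)
    m
  })
  s
}
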