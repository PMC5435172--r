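#' Arc length of a planar polyline
#'
#' Sums consecutive Euclidean distances along an ordered set of planar
#' points. All distances in this package are computed on polylines (never
#' from analytic curve parameters), so simulated and digitized specimens
#' are measured identically.
#'
#' @param points A numeric matrix with two columns (x, y) and at least two
#'   rows, ordered along the curve.
#' @return Total arc length (mm). Zero iff all points coincide.
#' @examples
#' polyline_arc_length(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
polyline_arc_length <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 2L) {
    stop("polyline_arc_length() needs at least 2 points", call. = FALSE)
  }
  d <- diff(points)
  sum(sqrt(d[, 1L]^2 + d[, 2L]^2))
}

# Coerce to an n x 2 numeric matrix, accepting list-of-pairs input from JSON.
as_point_matrix <- function(points) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, lapply(points, as.numeric))
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) {
    stop("points must have two columns (x, y)", call. = FALSE)
  }
  if (any(!is.finite(points))) {
    stop("points contain non-finite coordinates", call. = FALSE)
  }
  dimnames(points) <- NULL
  points
}

# Cumulative arc length (first entry 0) along an open polyline.
cum_arc_length <- function(points) {
  d <- diff(points)
  c(0, cumsum(sqrt(d[, 1L]^2 + d[, 2L]^2)))
}

# Perimeter of a closed polyline stored without a repeated end vertex.
closed_perimeter <- function(points) {
  polyline_arc_length(rbind(points, points[1L, , drop = FALSE]))
}

# Arc length along a closed outline walking forward (in storage order,
# wrapping past the last vertex) from vertex i to vertex j.
arc_between <- function(points, i, j) {
  n <- nrow(points)
  if (i == j) return(0)
  idx <- if (i < j) i:j else c(i:n, 1:j)
  polyline_arc_length(points[idx, , drop = FALSE])
}

# Quadratic Bezier sampled at n points (returns an n x 2 matrix).
quadratic_bezier <- function(p0, p1, p2, n = 33L) {
  t <- seq(0, 1, length.out = n)
  u <- 1 - t
  cbind(
    u^2 * p0[1L] + 2 * t * u * p1[1L] + t^2 * p2[1L],
    u^2 * p0[2L] + 2 * t * u * p1[2L] + t^2 * p2[2L]
  )
}

# Area, centroid and central second moments of a simple closed polygon
# (Green's theorem). Used to find the principal axis of an outline so
# that distorted specimens are measured along their own long axis.
polygon_moments <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  area <- sum(cr) / 2
  if (abs(area) < .Machine$double.eps * 100) {
    stop("degenerate outline: polygon area is zero", call. = FALSE)
  }
  cx <- sum((x + xn) * cr) / (6 * area)
  cy <- sum((y + yn) * cr) / (6 * area)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12 - area * cx^2
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12 - area * cy^2
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24 -
    area * cx * cy
  list(area = abs(area), centroid = c(cx, cy),
       ixx = abs(ixx), iyy = abs(iyy), ixy = if (area > 0) ixy else -ixy)
}

# Unit vector of the outline's principal (long) axis.
principal_axis <- function(points) {
  m <- polygon_moments(points)
  cov <- matrix(c(m$ixx, m$ixy, m$ixy, m$iyy), 2L)
  ev <- eigen(cov, symmetric = TRUE)
  ax <- ev$vectors[, 1L]
  if (ax[1L] < 0) ax <- -ax  # orient toward +x for reproducibility
  ax
}

# Extents of a point set along an axis (unit vector) and its perpendicular.
axis_extents <- function(points, axis) {
  proj_l <- points %*% axis
  proj_w <- points %*% c(-axis[2L], axis[1L])
  c(length = diff(range(proj_l)), width = diff(range(proj_w)))
}

# TRUE iff segments a1-a2 and b1-b2 properly intersect (shared endpoints
# do not count). Orientation-sign test.
segments_cross <- function(a1, a2, b1, b2) {
  orient <- function(p, q, r) {
    (q[1L] - p[1L]) * (r[2L] - p[2L]) - (q[2L] - p[2L]) * (r[1L] - p[1L])
  }
  d1 <- orient(b1, b2, a1); d2 <- orient(b1, b2, a2)
  d3 <- orient(a1, a2, b1); d4 <- orient(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# TRUE iff two polylines cross (any pair of segments properly intersects).
polylines_cross <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na - 1L)) {
    for (j in seq_len(nb - 1L)) {
      if (segments_cross(a[i, ], a[i + 1L, ], b[j, ], b[j + 1L, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}
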