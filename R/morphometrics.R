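#' Total length and width of a specimen
#'
#' Extent of the outline along its own principal axis (length) and the
#' perpendicular axis (width). The principal axis is estimated from the
#' outline's second area moments rather than trusted from construction,
#' so rotated or distorted specimens are measured consistently.
#'
#' @param s A `specimen`.
#' @return Extent in mm.
#' @export
measure_total_length <- function(s) {
  unname(outline_extents(s)["length"])
}

#' @rdname measure_total_length
#' @export
measure_total_width <- function(s) {
  unname(outline_extents(s)["width"])
}

outline_extents <- function(s) {
  pts <- s$outline$points
  if (nrow(pts) < 3L) stop("degenerate outline", call. = FALSE)
  axis_extents(pts, principal_axis(pts))
}

#' Module length at the midline (MLM)
#'
#' Straight-line distance between the consecutive midline anchors
#' bounding the module; the posterior-most module is bounded by the
#' posterior pole.
#'
#' @param s A `specimen`.
#' @param index Module index (1 = anterior-most).
#' @param side `"left"` or `"right"`.
#' @return Distance in mm.
#' @export
measure_mlm <- function(s, index, side = "left") {
  check_module_index(s, index)
  m <- module_lookup(s, index, side)
  post <- if (index < s$n_modules_true) {
    module_lookup(s, index + 1L, side)$midline_anchor
  } else {
    s$outline$points[s$posterior_pole_index, ]
  }
  sqrt(sum((m$midline_anchor - post)^2))
}

#' Module length at the outer margin (MLOM)
#'
#' Straight-line (chord) distance between the two outer-margin anchors
#' bounding the module on the given side.
#'
#' @inheritParams measure_mlm
#' @return Chord length in mm.
#' @export
measure_mlom <- function(s, index, side = "left") {
  check_module_index(s, index)
  iv <- margin_interval(s, index, side)
  sqrt(sum((iv$anterior - iv$posterior)^2))
}

#' Module width (MW)
#'
#' Arc length along the module's sinuous medial path from the midline to
#' the outer edge (not the straight-line distance: bent anterior modules
#' are longer along their path than across it).
#'
#' @inheritParams measure_mlm
#' @return Arc length in mm.
#' @export
measure_mw <- function(s, index, side = "left") {
  check_module_index(s, index)
  polyline_arc_length(module_lookup(s, index, side)$medial_curve)
}

check_module_index <- function(s, index) {
  if (!is.numeric(index) || length(index) != 1L || index < 1L ||
      index > s$n_modules_true) {
    stop(sprintf("module index %s out of range 1..%d",
                 toString(index), s$n_modules_true), call. = FALSE)
  }
  invisible(TRUE)
}

#' Outer-margin length of the anterior-most unit (AMU)
#'
#' Arc length of the AMU's margin interval: the contiguous anterior cap
#' of the outline spanning both sides. Arc length (not a chord) is used
#' because a chord across the anterior cap would cut through the body and
#' systematically understate the feature; module MLOM, by contrast, is a
#' chord. This measurement-convention asymmetry is recorded in the
#' measurement record.
#'
#' @param s A `specimen`.
#' @return Arc length in mm.
#' @export
measure_amu <- function(s) {
  idx <- s$amu$arc_point_indices
  if (length(idx) < 2L) stop("specimen has no AMU arc", call. = FALSE)
  polyline_arc_length(s$outline$points[idx, , drop = FALSE])
}

#' Measure one specimen with the full protocol
#'
#' Applies the grain-size resolution limit, then measures every resolved
#' module on both sides (MLM, MLOM, MW) together with the specimen-level
#' characters (TL, TW, AMU margin length). The measurable fraction —
#' observed over true module count — determines whether the record is
#' eligible for module-level statistics (threshold > 0.75: module
#' features must be measurable for more than three quarters of the
#' modules).
#'
#' @param s A `specimen`.
#' @param delta Resolution limit in mm (default 0: fully resolved).
#' @param eligibility_threshold Minimum measurable fraction for
#'   module-level eligibility (default 0.75, strict inequality).
#' @return A `measurement_record`: specimen-level fields plus a
#'   `modules` data frame with one row per module-side. An unmeasurable
#'   specimen yields a flagged record, not an error.
#' @export
measure_specimen <- function(s, delta = 0, eligibility_threshold = 0.75) {
  s <- apply_resolution_limit(s, delta)
  n_obs <- s$n_modules_observed
  n_true <- s$n_modules_true
  frac <- if (n_true > 0L) n_obs / n_true else 0

  modules <- if (n_obs >= 1L) {
    do.call(rbind, lapply(seq_len(n_obs), function(i) {
      do.call(rbind, lapply(c("left", "right"), function(side) {
        data.frame(module_index = i, side = side,
                   mlm_mm = measure_mlm(s, i, side),
                   mlom_mm = measure_mlom(s, i, side),
                   mw_mm = measure_mw(s, i, side))
      }))
    }))
  } else {
    data.frame(module_index = integer(), side = character(),
               mlm_mm = numeric(), mlom_mm = numeric(), mw_mm = numeric())
  }

  structure(
    list(specimen_id = s$specimen_id,
         tl_mm = measure_total_length(s),
         tw_mm = measure_total_width(s),
         n_modules_observed = n_obs,
         n_modules_true = n_true,
         amu_margin_mm = measure_amu(s),
         measurable_fraction = frac,
         module_stats_eligible = frac > eligibility_threshold && n_obs >= 1L,
         unmeasurable = isTRUE(s$unmeasurable),
         amu_convention = "arc",
         modules = modules),
    class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf(
    "<measurement %s> TL %.2f, TW %.2f mm; %d/%d modules observed%s\n",
    x$specimen_id, x$tl_mm, x$tw_mm, x$n_modules_observed,
    x$n_modules_true,
    if (x$module_stats_eligible) "" else " (not module-eligible)"))
  invisible(x)
}

#' Measure a whole population
#'
#' @param pop List of `specimen` objects.
#' @param delta Resolution limit in mm applied to every specimen.
#' @param eligibility_threshold Passed to [measure_specimen()].
#' @return List of `measurement_record` objects.
#' @export
measure_population <- function(pop, delta = 0, eligibility_threshold = 0.75) {
  lapply(pop, measure_specimen, delta = delta,
         eligibility_threshold = eligibility_threshold)
}

# Summed left+right MLOM per module for a measurement record,
# anterior -> posterior. Returns a named numeric vector.
record_mlom_sums <- function(rec) {
  mods <- rec$modules
  if (nrow(mods) == 0L) return(numeric())
  idx <- sort(unique(mods$module_index))
  vapply(idx, function(i) {
    sum(mods$mlom_mm[mods$module_index == i])
  }, numeric(1))
}
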