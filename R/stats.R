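#' Ordinary least-squares fit with F- and t-tests
#'
#' Simple linear regression, optionally through the origin. R^2 is
#' 1 - SSres/SStot with SStot about the mean for the intercept model and
#' about zero for the through-origin model (the standard convention, as
#' reported by [stats::lm()]); classical F- and slope-t statistics with
#' their p-values accompany the fit.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, with
#'   non-degenerate x.
#' @param through_origin Fit y = b x instead of y = a + b x.
#' @return A `regression_result`: slope, intercept (NA for
#'   through-origin), r_squared, f_statistic, f_pvalue, t_statistic_slope,
#'   t_pvalue_slope, n, model_form.
#' @export
ols_fit <- function(x, y, through_origin = FALSE) {
  check_xy(x, y)
  if (stats::var(x) <= 0) stop("degenerate x: zero variance", call. = FALSE)
  fit <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  slope_row <- "x"
  fstat <- sm$fstatistic
  f_p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  # constant response: no variance to explain, R^2 is 0 by convention
  # (summary.lm divides rounding-noise sums of squares there)
  r2 <- if (!through_origin && stats::var(y) == 0) 0
        else if (is.finite(sm$r.squared)) sm$r.squared
        else 0
  structure(
    list(slope = unname(co[slope_row, "Estimate"]),
         intercept = if (through_origin) NA_real_
                     else unname(co["(Intercept)", "Estimate"]),
         r_squared = r2,
         f_statistic = unname(fstat[1L]),
         f_pvalue = unname(f_p),
         t_statistic_slope = unname(co[slope_row, "t value"]),
         t_pvalue_slope = unname(co[slope_row, "Pr(>|t|)"]),
         n = length(x),
         model_form = if (through_origin) "linear_through_origin"
                      else "linear"),
    class = "regression_result")
}

check_xy <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Power-law fit y = a x^b by log-log least squares
#'
#' Fits on log10 scale; `r_squared` is the coefficient of determination
#' on the log-log scale (the usual spreadsheet convention), and
#' `r_squared_linear` additionally reports the linear-scale R^2 of the
#' back-transformed curve for transparency.
#'
#' @param x,y Positive numeric vectors (n >= 3).
#' @return A `regression_result` with `coef_a`, `coef_b` (`slope` is b),
#'   `model_form = "power_loglog"`.
#' @export
power_fit <- function(x, y) {
  check_xy(x, y)
  if (any(x <= 0) || any(y <= 0)) {
    stop("power_fit requires strictly positive x and y", call. = FALSE)
  }
  res <- ols_fit(log10(x), log10(y))
  a <- 10^res$intercept
  b <- res$slope
  yhat <- a * x^b
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  res$coef_a <- a
  res$coef_b <- b
  res$r_squared_linear <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  res$model_form <- "power_loglog"
  res
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<%s fit> slope %.4g%s, R^2 %.4f, F = %.4g (p = %.3g), n = %d\n",
    x$model_form, x$slope,
    if (is.na(x$intercept)) "" else sprintf(", intercept %.4g", x$intercept),
    x$r_squared, x$f_statistic, x$f_pvalue, x$n))
  invisible(x)
}

#' Adjacent-module outer-margin increase statistic
#'
#' For each module j with a posterior neighbour j + 1, using the summed
#' left + right outer-margin lengths S_j:
#' increase_j = 100 * (S_j - S_{j+1}) / S_j (percent). The statistic is
#' pooled over all (specimen, module-pair) combinations of the
#' module-eligible records into a single mean and SD; negative increases
#' (posterior module larger) are retained. Per-specimen means are also
#' returned. On an exact geometric series with ratio r every pair gives
#' 100 * (1 - r).
#'
#' @param records List of `measurement_record` objects; only records with
#'   `module_stats_eligible` and at least two modules contribute.
#' @return List with `mean_pct`, `sd_pct`, `n_pairs`, `increases_pct`
#'   (all pooled values) and `per_specimen` (data frame of per-specimen
#'   means).
#' @export
mlom_increase_statistic <- function(records) {
  records <- as_record_list(records)
  incs <- list()
  per_spec <- list()
  n_skipped <- 0L
  for (rec in records) {
    if (!isTRUE(rec$module_stats_eligible)) next
    s <- record_mlom_sums(rec)
    if (length(s) < 2L) next
    lead <- s[-length(s)]
    lag <- s[-1L]
    ok <- lead > 0
    n_skipped <- n_skipped + sum(!ok)
    vals <- 100 * (lead[ok] - lag[ok]) / lead[ok]
    if (length(vals)) {
      incs[[length(incs) + 1L]] <- vals
      per_spec[[length(per_spec) + 1L]] <-
        data.frame(specimen_id = rec$specimen_id, mean_pct = mean(vals),
                   n_pairs = length(vals))
    }
  }
  all_vals <- unlist(incs)
  if (is.null(all_vals)) all_vals <- numeric()
  list(mean_pct = if (length(all_vals)) mean(all_vals) else NA_real_,
       sd_pct = if (length(all_vals) > 1L) stats::sd(all_vals) else 0,
       n_pairs = length(all_vals),
       n_skipped = n_skipped,
       increases_pct = all_vals,
       per_specimen = if (length(per_spec)) do.call(rbind, per_spec)
                      else data.frame(specimen_id = character(),
                                      mean_pct = numeric(),
                                      n_pairs = integer()))
}

#' Anterior-most unit versus first true module
#'
#' Ratio of the AMU outer-margin length to the summed left + right
#' outer-margin length of the first true module, with strict-inequality
#' counts of specimens exceeding 20% and 50% excess.
#'
#' @param records List of `measurement_record` objects (module-eligible
#'   records with a measurable first module contribute).
#' @return List with `n_eligible`, `count_gt20`, `count_gt50` and the
#'   per-specimen `ratios` data frame.
#' @export
amu_comparison <- function(records) {
  records <- as_record_list(records)
  rows <- list()
  for (rec in records) {
    if (!isTRUE(rec$module_stats_eligible)) next
    s <- record_mlom_sums(rec)
    if (length(s) < 1L || !is.finite(rec$amu_margin_mm) || s[1L] <= 0) next
    rows[[length(rows) + 1L]] <-
      data.frame(specimen_id = rec$specimen_id,
                 ratio = rec$amu_margin_mm / s[1L])
  }
  ratios <- if (length(rows)) do.call(rbind, rows)
            else data.frame(specimen_id = character(), ratio = numeric())
  list(n_eligible = nrow(ratios),
       count_gt20 = sum(ratios$ratio > 1.20),
       count_gt50 = sum(ratios$ratio > 1.50),
       ratios = ratios)
}

#' Normalize a module number to total length
#'
#' Module position rescaled to the body axis: index / n_modules *
#' total_length (mm), so profiles from specimens of different sizes and
#' counts are directly comparable.
#'
#' @param index Module index (1 <= index <= n_modules); vectorized.
#' @param n_modules Total module count.
#' @param total_length TL in mm (> 0).
#' @return Normalized position in mm.
#' @export
normalized_module_number <- function(index, n_modules, total_length) {
  if (any(index < 1L) || any(index > n_modules)) {
    stop("module index out of range", call. = FALSE)
  }
  stopifnot_msg(all(total_length > 0), "total_length must be > 0")
  index / n_modules * total_length
}

#' Moving average along a profile
#'
#' Two-point moving averages are the standard trend line for per-module
#' profiles; the window is exposed for generality.
#'
#' @param values Numeric vector.
#' @param window Window width (1 <= window <= length(values)).
#' @return Vector of length `length(values) - window + 1`.
#' @export
moving_average <- function(values, window = 2L) {
  window <- as.integer(window)
  if (window < 1L || window > length(values)) {
    stop("window must be between 1 and length(values)", call. = FALSE)
  }
  out <- stats::filter(values, rep(1 / window, window), sides = 1)
  as.numeric(out[window:length(values)])
}

as_record_list <- function(records) {
  if (inherits(records, "measurement_record")) return(list(records))
  records
}

#' Population-level growth summary
#'
#' Assembles every statistic of the analysis pipeline over a set of
#' measurement records: length/width descriptives; the length-width
#' isometry regression fitted both with a free intercept and through the
#' origin (the headline R^2 is the free-intercept one, with the
#' through-origin slope as the width-ratio estimate); linear and
#' power-law fits of module number against total length; the regression
#' of per-specimen mean midline module length on total length; the pooled
#' adjacent-module increase statistic; and the AMU comparison counts.
#'
#' @param records List of `measurement_record` objects (>= 3 with
#'   measurable size).
#' @return A `population_summary` list.
#' @export
summarize_population <- function(records) {
  records <- as_record_list(records)
  sized <- Filter(function(r) is.finite(r$tl_mm) && is.finite(r$tw_mm) &&
                    !isTRUE(r$unmeasurable), records)
  if (length(sized) < 3L) {
    stop("need at least 3 size-measured records", call. = FALSE)
  }
  tl <- vapply(sized, function(r) r$tl_mm, numeric(1))
  tw <- vapply(sized, function(r) r$tw_mm, numeric(1))

  counted <- Filter(function(r) r$n_modules_observed >= 3L, sized)
  n_cnt <- vapply(counted, function(r) as.numeric(r$n_modules_observed),
                  numeric(1))
  tl_cnt <- vapply(counted, function(r) r$tl_mm, numeric(1))

  eligible <- Filter(function(r) isTRUE(r$module_stats_eligible), records)
  mlm_mean <- vapply(eligible, function(r) mean(r$modules$mlm_mm), numeric(1))
  tl_elig <- vapply(eligible, function(r) r$tl_mm, numeric(1))

  inc <- mlom_increase_statistic(records)
  amu <- amu_comparison(records)

  structure(
    list(n_total = length(records),
         n_size_measured = length(sized),
         n_module_counted = length(counted),
         tl_mean = mean(tl), tl_min = min(tl), tl_max = max(tl),
         tw_mean = mean(tw), tw_min = min(tw), tw_max = max(tw),
         lw_regression = ols_fit(tl, tw),
         lw_regression_origin = ols_fit(tl, tw, through_origin = TRUE),
         nmod_linear = if (length(n_cnt) >= 3L) ols_fit(tl_cnt, n_cnt)
                       else NULL,
         nmod_power = if (length(n_cnt) >= 3L) power_fit(tl_cnt, n_cnt)
                      else NULL,
         mlm_vs_tl = if (length(mlm_mean) >= 3L) ols_fit(tl_elig, mlm_mean)
                     else NULL,
         mlom_increase_mean_pct = inc$mean_pct,
         mlom_increase_sd_pct = inc$sd_pct,
         mlom_increase_n_pairs = inc$n_pairs,
         amu_n_eligible = amu$n_eligible,
         amu_gt20_count = amu$count_gt20,
         amu_gt50_count = amu$count_gt50),
    class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population summary> n = %d (%d sized, %d module-counted)\n",
              x$n_total, x$n_size_measured, x$n_module_counted))
  cat(sprintf("  TL %.2f mm [%.2f, %.2f]; TW %.2f mm [%.2f, %.2f]\n",
              x$tl_mean, x$tl_min, x$tl_max, x$tw_mean, x$tw_min, x$tw_max))
  cat(sprintf("  TL-TW: R^2 = %.4f (free), slope %.4f (origin)\n",
              x$lw_regression$r_squared, x$lw_regression_origin$slope))
  if (!is.null(x$nmod_linear)) {
    cat(sprintf("  N modules vs TL: R^2 = %.3f linear, %.3f power (log-log)\n",
                x$nmod_linear$r_squared, x$nmod_power$r_squared))
  }
  cat(sprintf("  MLOM increase: %.2f +/- %.2f%% (%d pairs)\n",
              x$mlom_increase_mean_pct, x$mlom_increase_sd_pct,
              x$mlom_increase_n_pairs))
  cat(sprintf("  AMU > +20%%: %d, > +50%%: %d of %d\n",
              x$amu_gt20_count, x$amu_gt50_count, x$amu_n_eligible))
  invisible(x)
}
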