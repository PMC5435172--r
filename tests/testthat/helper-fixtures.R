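# Shared fixtures. Noise-free parameters expose the generator's exact
# construction; the coarse outline keeps property loops fast while the
# defaults (2048 vertices) are exercised where resolution matters.

noise_free_params <- function(...) {
  args <- utils::modifyList(
    list(width_noise_cv = 0, module_count_dispersion = 0,
         n_vertices = 1024L),
    list(...))
  do.call(growth_params, args)
}

# Brute-force OLS by the normal equations, independent of stats::lm().
brute_force_ols <- function(x, y, through_origin = FALSE) {
  n <- length(x)
  if (through_origin) {
    slope <- sum(x * y) / sum(x * x)
    res <- y - slope * x
    ss_res <- sum(res^2)
    ss_tot <- sum(y^2)
    df <- n - 1L
    se <- sqrt(ss_res / df / sum(x * x))
    intercept <- NA_real_
  } else {
    xb <- mean(x); yb <- mean(y)
    sxx <- sum((x - xb)^2)
    slope <- sum((x - xb) * (y - yb)) / sxx
    intercept <- yb - slope * xb
    res <- y - intercept - slope * x
    ss_res <- sum(res^2)
    ss_tot <- sum((y - yb)^2)
    df <- n - 2L
    se <- sqrt(ss_res / df / sxx)
  }
  f <- (ss_tot - ss_res) / (ss_res / df)
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot,
       f_statistic = f,
       f_pvalue = stats::pf(f, 1, df, lower.tail = FALSE),
       t_statistic_slope = slope / se,
       t_pvalue_slope = 2 * stats::pt(abs(slope / se), df,
                                      lower.tail = FALSE))
}

# Hand-built measurement record with prescribed summed MLOM per module
# (split equally between sides), for exercising the statistics on known
# series without geometry in the way.
record_from_mlom_sums <- function(sums, specimen_id = "synthetic",
                                  amu = NA_real_, tl = 20, tw = 17) {
  n <- length(sums)
  mods <- data.frame(
    module_index = rep(seq_len(n), each = 2L),
    side = rep(c("left", "right"), n),
    mlm_mm = 1, mlom_mm = rep(sums / 2, each = 2L), mw_mm = 1)
  structure(
    list(specimen_id = specimen_id, tl_mm = tl, tw_mm = tw,
         n_modules_observed = n, n_modules_true = n,
         amu_margin_mm = amu, measurable_fraction = 1,
         module_stats_eligible = TRUE, unmeasurable = FALSE,
         amu_convention = "arc", modules = mods),
    class = "measurement_record")
}
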