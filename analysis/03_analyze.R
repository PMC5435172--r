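#!/usr/bin/env Rscript
# Step 3: population statistics.
#
# Reads the measurement table and computes every population-level
# statistic: length-width isometry (free-intercept and through-origin
# OLS with F/t tests), linear and power-law module-number scaling, mean
# midline module length vs total length, the pooled adjacent-module
# outer-margin increase statistic, and the AMU comparison counts.
# Writes the summary JSON and diagnostic figures (PDF).

suppressPackageStartupMessages(library(dickinsonia))

recs <- read_measurements("results/measurements.csv")
message(sprintf("analyzing %d measurement records ...", length(recs)))

sm <- summarize_population(recs)
print(sm)
write_summary_json(sm, "results/summary.json", seed = 20260930L)

tl <- vapply(recs, function(r) r$tl_mm, numeric(1))
tw <- vapply(recs, function(r) r$tw_mm, numeric(1))
nmod <- vapply(recs, function(r) r$n_modules_observed, integer(1))

grDevices::pdf("results/figures.pdf", width = 7, height = 5)

plot(tl, tw, pch = 16, cex = 0.5, col = "#00000070",
     xlab = "Total length (mm)", ylab = "Total width (mm)",
     main = sprintf("Length-width isometry (R² = %.3f)",
                    sm$lw_regression$r_squared))
abline(0, sm$lw_regression_origin$slope, col = "firebrick", lwd = 2)

plot(tl, nmod, pch = 16, cex = 0.5, col = "#00000070",
     xlab = "Total length (mm)", ylab = "Observed number of modules",
     main = sprintf("Module-number scaling (R²: linear %.2f, power %.2f)",
                    sm$nmod_linear$r_squared, sm$nmod_power$r_squared))
xx <- seq(min(tl), max(tl), length.out = 200)
lines(xx, sm$nmod_linear$intercept + sm$nmod_linear$slope * xx,
      col = "steelblue", lwd = 2)
lines(xx, sm$nmod_power$coef_a * xx^sm$nmod_power$coef_b,
      col = "firebrick", lwd = 2)
legend("topleft", c("linear", "power"), lwd = 2,
       col = c("steelblue", "firebrick"), bty = "n")

# per-module profiles of five mid-sized eligible specimens, with the
# two-point moving-average trend lines
eligible <- Filter(function(r) r$module_stats_eligible &&
                     r$n_modules_observed >= 8, recs)
show <- eligible[order(abs(vapply(eligible, function(r) r$tl_mm,
                                  numeric(1)) - 24.31))][1:5]
xmax <- max(vapply(show, function(r) r$tl_mm, numeric(1)))
for (feature in c("mlom_mm", "mw_mm")) {
  ylim <- range(unlist(lapply(show, function(r) r$modules[[feature]])))
  plot(NULL, xlim = c(0, xmax), ylim = ylim,
       xlab = "Normalized module position (mm)",
       ylab = sprintf("%s (mm)", toupper(sub("_mm", "", feature))),
       main = "Anterior (left) to posterior (right)")
  cols <- grDevices::hcl.colors(5, "Dark 3")
  for (i in seq_along(show)) {
    r <- show[[i]]
    left <- r$modules[r$modules$side == "left", ]
    xpos <- normalized_module_number(left$module_index,
                                     r$n_modules_observed, r$tl_mm)
    points(xpos, left[[feature]], col = cols[i], pch = 16, cex = 0.7)
    lines(xpos[-1] - diff(xpos) / 2, moving_average(left[[feature]], 2),
          col = cols[i], lty = 2)
  }
}
invisible(grDevices::dev.off())

message("wrote results/summary.json and results/figures.pdf")
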