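#!/usr/bin/env Rscript
# Step 4: a single ontogeny under terminal addition.
#
# Grows one individual from 5 mm through 20 ten-percent length
# increments, tracking module insertion at the posterior, the uniform
# midline module length, and the per-module expansion of outer-margin
# lengths. Writes a per-step table and start/middle/end SVG renderings.

suppressPackageStartupMessages(library(dickinsonia))

params <- growth_params(width_noise_cv = 0, module_count_dispersion = 0,
                        rng_seed = 20260930L)
traj <- simulate_growth_trajectory(5, 20, params)

tab <- do.call(rbind, lapply(traj, function(sn) {
  data.frame(step = sn$step,
             total_length_mm = sn$total_length_mm,
             n_modules = sn$n_modules_true,
             mlm_mm = sn$mlm_mm,
             mlom_anterior_mm = measure_mlom(sn$specimen, 1),
             amu_margin_mm = measure_amu(sn$specimen))
}))
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/trajectory.csv", row.names = FALSE)

message(sprintf("grew TL %.1f -> %.1f mm; modules %d -> %d",
                tab$total_length_mm[1], tab$total_length_mm[nrow(tab)],
                tab$n_modules[1], tab$n_modules[nrow(tab)]))
message(sprintf("anterior module MLOM expanded %.2f -> %.2f mm (monotone: %s)",
                tab$mlom_anterior_mm[1], tab$mlom_anterior_mm[nrow(tab)],
                all(diff(tab$mlom_anterior_mm) >= 0)))

for (i in c(1L, 11L, 21L)) {
  render_specimen_svg(traj[[i]]$specimen,
                      sprintf("results/trajectory_step_%02d.svg", i - 1L))
}
message("wrote results/trajectory.csv and trajectory SVGs")
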