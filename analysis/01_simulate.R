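#!/usr/bin/env Rscript
# Step 1: simulate a fossil-like sample.
#
# Generates 988 ovoid modular specimens under the default growth model
# (isometric outline, sqrt module-number scaling, geometric margin decay
# r = 0.96), then applies the completeness filter at 538/988 — the
# fraction of examined specimens complete enough to measure — so the
# retained sample emulates a measured census. Writes the complete
# population as specimen JSON and renders one mid-sized specimen as SVG.

suppressPackageStartupMessages(library(dickinsonia))

seed <- 20260930L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

message("simulating 988 specimens ...")
pop_all <- generate_population(988, growth_params(rng_seed = seed))

filt <- apply_completeness_filter(
  pop_all, taphonomy_params(completeness = 538 / 988, rng_seed = seed + 1L))
message(sprintf("completeness filter retained %d of %d specimens",
                length(filt$complete), length(pop_all)))

write_specimens(filt$complete, file.path(out_dir, "population.json"))

tl <- vapply(filt$complete, function(s) s$outline$total_length_mm, numeric(1))
message(sprintf("retained TL: mean %.2f mm, range [%.2f, %.2f] mm",
                mean(tl), min(tl), max(tl)))

show <- filt$complete[[which.min(abs(tl - 24.31))]]
render_specimen_svg(show, file.path(out_dir, "example_specimen.svg"))
message("wrote results/population.json and results/example_specimen.svg")
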