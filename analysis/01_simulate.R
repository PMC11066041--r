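#!/usr/bin/env Rscript
# Step 1: simulate the multi-city daily panel and write the three-table
# layout (admissions, air quality, meteorology) plus the ground-truth
# sidecar that later steps score against.

source("analysis/00_config.R")

cfg <- analysis_sim_config()
sim <- simulate_panel(cfg)
paths <- write_panel_tables(sim, cfg, data_dir)

cat(sprintf("simulated %d cities x %d days = %d rows\n",
            cfg$n_cities, cfg$n_days, nrow(sim$panel)))
cat(sprintf("admissions: mean %.1f/day (dispersion target phi = %.2f)\n",
            mean(sim$panel$y), cfg$phi))
cat(sprintf("pollutant: median %.1f ug/m3, IQR [%.1f, %.1f]\n",
            median(sim$panel$x), quantile(sim$panel$x, .25),
            quantile(sim$panel$x, .75)))
cat(sprintf("truth: %s surface, max lag %d, reference %.0f ug/m3\n",
            sim$surface$family, sim$surface$max_lag, sim$surface$x_ref))
cat("wrote:", paste(basename(paths), collapse = ", "), "->", data_dir, "\n")
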