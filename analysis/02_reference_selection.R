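#!/usr/bin/env Rscript
# Step 2: reference-city model optimization, per period. Enumerates every
# covariate subset crossed with the hyperparameter grid, ranks by QAIC
# (reference dispersion from the most complex candidate) and applies the
# delta-QAIC < 2 parsimony rule. Writes the full QAIC table and the frozen
# configuration consumed by step 3.

source("analysis/00_config.R")

grid <- analysis_grid()
for (period in periods) {
  panel <- read_period_panels(period)[[cities[1]]]
  opt <- optimize_dlnm(panel, grid)
  sel <- opt$selected
  cat(sprintf(
    "[%s] %d candidates; best QAIC %.1f; selected: lag %d, df_p %d, df_l %d, covariates {%s}\n",
    period, nrow(opt$table), sel$qaic, sel$max_lag, sel$df_p, sel$df_l,
    sel$covariates
  ))
  write.csv(opt$table,
            file.path(out_dir, sprintf("qaic_table_%s.csv", period)),
            row.names = FALSE)
  frozen <- list(
    covariates = strsplit(sel$covariates, ",")[[1]],
    max_lag = sel$max_lag, df_p = sel$df_p, df_l = sel$df_l,
    boundary = opt$refit$boundary,
    x_ref = median(panel$x),
    phi_ref = opt$phi_ref
  )
  jsonlite::write_json(frozen,
                       file.path(out_dir, sprintf("selected_model_%s.json", period)),
                       auto_unbox = TRUE, digits = NA)
}
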