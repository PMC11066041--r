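#!/usr/bin/env Rscript
# Step 4: fixed-effect multivariate meta-analysis of the city-level
# cross-basis coefficient blocks, per period.

source("analysis/00_config.R")

for (period in periods) {
  ests <- jsonlite::read_json(
    file.path(out_dir, sprintf("city_estimates_%s.json", period)),
    simplifyVector = TRUE)
  studies <- lapply(seq_len(nrow(ests)), function(i) {
    list(beta = ests$beta[[i]], vcov = ests$vcov[[i]], label = ests$city[i])
  })
  pooled <- fixed_effect_mvmeta(studies)
  cat(sprintf("[%s] pooled %d cities, d = %d; heterogeneity Q = %.2f on %d df\n",
              period, length(studies), length(pooled$beta), pooled$Q,
              pooled$df_Q))
  jsonlite::write_json(
    list(beta = unname(pooled$beta), vcov = unname(pooled$vcov),
         Q = pooled$Q, df_Q = pooled$df_Q, labels = pooled$labels),
    file.path(out_dir, sprintf("pooled_estimate_%s.json", period)),
    auto_unbox = TRUE, digits = NA)
}
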