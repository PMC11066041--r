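#!/usr/bin/env Rscript
# Step 3: fit every city at the frozen configuration (hyperparameters,
# covariate subset and predictor knots all inherited from the reference
# city), per period. Writes the city-level cross-basis coefficient blocks
# and their variance-covariance matrices for the pooling step.

source("analysis/00_config.R")

for (period in periods) {
  frozen <- jsonlite::read_json(
    file.path(out_dir, sprintf("selected_model_%s.json", period)),
    simplifyVector = TRUE)
  panels <- read_period_panels(period)
  ests <- lapply(cities, function(ct) {
    f <- fit_city(panels[[ct]], frozen$covariates, frozen$max_lag,
                  frozen$df_p, frozen$df_l, boundary = frozen$boundary)
    blk <- coef_block(f$fit, "cb")
    cat(sprintf("[%s] %s: n = %d, phi = %.2f\n",
                period, ct, f$fit$n, f$fit$dispersion))
    list(city = ct, beta = unname(blk$beta), vcov = unname(blk$vcov),
         dispersion = f$fit$dispersion, n = f$fit$n)
  })
  jsonlite::write_json(ests,
                       file.path(out_dir, sprintf("city_estimates_%s.json", period)),
                       auto_unbox = TRUE, digits = NA)
}
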