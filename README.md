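# lagriskr

Two-stage multi-city time-series analysis of particulate matter and daily
hospital admissions, for environmental-epidemiology practitioners who need
the full pipeline — distributed lag non-linear models (DLNMs), principled
model selection, and multi-city pooling — as tested, reusable functions.

## What it does

Stage one fits, per city, the quasi-Poisson DLNM

    log E(Y_t) = alpha + cb(x_t, ..., x_{t-L}; beta) + gamma' M_t + delta' S_t,
    V(Y_t) = phi * mu_t

where `cb` is a natural-cubic-spline cross-basis over exposure (df_p) and
lag (df_l, lags 0..L) with equally spaced knots, `M_t` is a subset of five
meteorological covariates (temperature, humidity, wind, diurnal temperature
range, precipitation) and `S_t` holds six Fourier harmonics of annual
seasonality. The covariate subset and the hyperparameters (L in 7..31,
df_p and df_l in 2..5 by default) are optimized jointly: every one of the
2^5 covariate masks is crossed with the hyperparameter grid, ranked by

    QAIC = -2 * logLik_Poisson / phi_ref + 2p

(reference dispersion from the most complex candidate), and the model
within 2 QAIC units of the minimum that is simplest wins. The selected
configuration — including the reference city's spline knots — is frozen for
all other cities.

Stage two pools the city-level cross-basis coefficient blocks by
fixed-effect multivariate meta-analysis,

    beta_pooled = (sum_j Vj^-1)^-1 sum_j Vj^-1 beta_j,

and reduces the pooled block to relative-risk summaries against a reference
concentration (the reference city's median): the overall cumulative
exposure-response curve, the exposure-lag surface, and per-lag effects at
the 10th/90th exposure percentiles, all with delta-method 95% intervals.

Because the admissions databases such analyses run on are
access-restricted, the package includes a synthetic multi-city panel
generator with a known exposure-lag-response surface (inverted-U in
concentration, geometric decay in lag), so every stage is testable by
parameter recovery.

## Worked example

The `analysis/` scripts run the whole workflow on a simulated 3-city,
2016–2020 panel, split into pre-pandemic (2016–2019) and pandemic (2020)
periods:

```sh
Rscript analysis/01_simulate.R            # write the three-table panel + truth
Rscript analysis/02_reference_selection.R # QAIC search on the reference city
Rscript analysis/03_city_fits.R           # frozen-configuration city fits
Rscript analysis/04_meta_pool.R           # fixed-effect multivariate pooling
Rscript analysis/05_associations.R        # RR curves, surface, extreme contrasts
```

which prints, among other things:

```
[pre] 1152 candidates; best QAIC 5888.4; selected: lag 14, df_p 2, df_l 2, covariates {tavg}
[pre] pooled 3 cities, d = 4; heterogeneity Q = 12.54 on 8 df
[pre] cumulative RR at q90 (61 ug/m3) = 0.973, at q10 (28 ug/m3) = 1.004
[pre] truth check: mean |logRR error| = 0.0339; 95% CI covers truth at 100% of grid points
```

Read: the reference-city search over 1152 candidates picked a 14-day lag
window with 2 spline df per dimension and temperature as the only
covariate; pooling the three cities gives a cumulative relative risk of
0.973 at the 90th exposure percentile versus the median (the simulated
truth is protective above ~60 ug/m3), and the pooled 95% band covers the
known true curve everywhere on the exposure grid. Tables land under
`results/`.

The same machinery is available programmatically:

```r
library(lagriskr)
cfg <- sim_config(n_cities = 3, seed = 1)
res <- run_two_stage(run_config(sim = cfg,
                                grid = search_grid(max_lags = c(7, 14),
                                                   df_p_values = 2:3,
                                                   df_l_values = 2:3)))
res$all$selection$selected   # winning candidate and its QAIC
res$all$pooled               # pooled estimate with heterogeneity Q
head(res$all$associations$overall)  # cumulative RR curve vs reference
```

## Layout

* `R/` — the package: simulator, panel IO, spline/Fourier/cross-basis
  construction, quasi-Poisson IRLS + QAIC, best-subset grid search,
  RR reduction, fixed-effect multivariate pooling, orchestration.
* `analysis/` — the numbered workflow scripts above.
* `vignettes/dlnm-two-stage.Rmd` — the methods vignette: model,
  conventions, generator design, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance tests, including
  independent oracles (truncated-power splines, Newton-Raphson Poisson,
  brute-force cross-basis, scalar inverse-variance pooling).
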