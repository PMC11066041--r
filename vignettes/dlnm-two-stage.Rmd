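---
title: "Two-stage distributed-lag non-linear modelling of particulate matter and daily admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage distributed-lag non-linear modelling of particulate matter and daily admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagriskr)
```

## The problem and the model

Short-term associations between ambient particulate matter (PM10, PM2.5, in
ug/m3) and daily hospital admissions are typically non-linear in
concentration and distributed over days to weeks of lag. `lagriskr`
implements the standard two-stage design for multi-city studies of this
kind. In stage one, each city's daily series is fitted with a distributed
lag non-linear model (DLNM) under a quasi-Poisson likelihood:

$$\log E(Y_t) \;=\; \alpha \;+\; \mathrm{cb}(x_t, \dots, x_{t-L};\, \beta)
\;+\; \gamma' M_t \;+\; \delta' S_t,
\qquad V(Y_t) = \phi\, \mu_t,$$

where $Y_t$ is the admission count on day $t$, $\mathrm{cb}$ is a
cross-basis in the exposure and lag dimensions with coefficient block
$\beta$, $M_t$ is a subset of five meteorological covariates (average
temperature, relative humidity, wind speed, diurnal temperature range,
precipitation) entering linearly, and $S_t$ is a Fourier seasonal vector
(six harmonics over a 365-day period by default). In stage two, the
city-level $(\hat\beta_j, \hat V_j)$ pairs are pooled by fixed-effect
multivariate meta-analysis and the pooled block is reduced to relative-risk
summaries.

## Cross-basis construction

The cross-basis pairs a natural cubic spline in the exposure dimension
(`df_p` columns) with a natural cubic spline over the integer lag grid
$0..L$ (`df_l` columns):

$$\mathrm{cb}_{t,(j,k)} \;=\; \sum_{l=0}^{L} R\big(x_{t-l}\big)_j \, C(l)_k,$$

giving `df_p * df_l` columns. Conventions, fixed once and used everywhere:

* **Knots** are equally spaced: interior knots at equal steps strictly
  between the boundary knots, in both dimensions; the lag knots sit on the
  untransformed lag scale (not log-lag, which other DLNM software often
  defaults to).
* **Boundary knots** of the predictor basis are the observed min/max of the
  exposure series the basis is built on (or an explicitly frozen range;
  see pooling below). Predictions outside the boundary are linear
  extrapolations and are flagged.
* **No intercept columns** in either marginal basis; the GLM intercept
  absorbs the constant. A consequence of omitting the lag-dimension
  intercept is that every lag-basis column vanishes at lag 0, so
  *lag-specific* effects at lag 0 are structurally zero. Cumulative
  summaries, which sum the basis over all lags, are unaffected; lag-curve
  plots should be read as anchored at RR = 1 on day 0.
* Days without a complete lag history (the first $L$ days) are dropped from
  fitting, not imputed.

`build_cross_basis()` is checked elementwise against a brute-force
quadruple loop over $(t, l, j, k)$, and the natural-spline span against an
independent truncated-power construction.

## Fitting and QAIC

`fit_quasipoisson()` maximises the Poisson log-likelihood by iteratively
reweighted least squares (quasi-Poisson point estimates coincide with
Poisson ML). Numerical conventions:

* convergence when the relative deviance change falls below $10^{-11}$
  (at most 100 iterations); rank-deficient designs are rejected with the
  collinear columns named rather than silently dropped;
* the dispersion is Pearson-based, $\hat\phi = \chi^2_P/(n-p)$, and scales
  the variance-covariance matrix $\hat V = \hat\phi\,(X'WX)^{-1}$;
* perfect fits (Pearson $\chi^2 \approx 0$) floor $\hat\phi$ at $10^{-8}$
  with a warning so QAIC stays finite in degenerate toy cases.

Model comparison uses the quasi-AIC

$$\mathrm{QAIC} = -\,2\,\ell_{\mathrm{Pois}}/\phi_{\mathrm{ref}} + 2p,$$

where $p$ counts all estimated regression coefficients including the
intercept (the dispersion is not counted), and $\phi_{\mathrm{ref}}$ is a
single reference dispersion shared by all candidates in one search,
estimated from the most complex candidate (all five covariates, largest
lag and degrees of freedom in the grid). A shared reference dispersion is
the standard quasi-likelihood model-selection convention; without it the
likelihood scale would shift between candidates and QAIC differences would
not be comparable.

## Covariate and hyperparameter optimization

`optimize_dlnm()` enumerates every covariate subset ($2^k$ masks over the
five meteorological factors, as a binary counter) crossed with the
hyperparameter grid — by default maximum lag 7..31 days and 2..5 degrees of
freedom in each dimension — and ranks all candidates by QAIC. Two choices
the selection contract leaves open are resolved as follows:

* **Common fitting window.** All candidates are fitted to the days with a
  full lag history for the *largest* lag in the grid, so every QAIC refers
  to the same response vector. Smaller-lag candidates could use more days,
  but then their likelihoods would not be comparable.
* **Joint search.** Covariate subsets and hyperparameters are optimized
  jointly over the full cross product (the literal reading of a best-subset
  step followed by per-subset tuning), not sequentially.

Selection applies the parsimony rule: among candidates within 2 QAIC units
of the minimum, the simplest wins. Simplicity is ordered by fewer
covariates, then smaller `df_p + df_l`, then smaller lag, then lower QAIC,
then enumeration order — the first key is the substantive rule, the rest
are deterministic tie-breaks so the search is a pure function of its
inputs. Candidates whose fit fails numerically are excluded with a logged
reason rather than aborting the search. The QAIC table is deterministic,
so parallel and serial evaluation give identical selections.

## Two-stage orchestration and pooling

`run_two_stage()` optimizes on the *reference city* (the first in the
panel list) only, then freezes the selected covariate subset,
hyperparameters, **and the reference city's predictor-basis knots** for
every other city. Freezing the knots goes slightly beyond freezing the
hyperparameters, but it is what makes the city-level coefficient blocks
refer to one common basis — a requirement for pooling them into a single
surface. The pooled estimate is the fixed-effect multivariate solution

$$\hat\beta \;=\; \Big(\sum_j V_j^{-1}\Big)^{-1} \sum_j V_j^{-1}\hat\beta_j,
\qquad
\hat V \;=\; \Big(\sum_j V_j^{-1}\Big)^{-1},$$

with the heterogeneity statistic
$Q = \sum_j (\hat\beta_j-\hat\beta)' V_j^{-1} (\hat\beta_j-\hat\beta)$ on
$(J-1)d$ degrees of freedom reported as a diagnostic. All inversions use
Cholesky factorizations; a study vcov with condition number above $10^{12}$
is rejected by name. Only the cross-basis block is pooled — covariate and
seasonal coefficients are city-specific nuisance. No random-effects
estimator is provided.

When a period split is configured (default: 2016–2019 versus 2020), the two
periods are analysed as fully independent runs, selection included. That is
the conservative choice where the design is ambiguous; sharing the selected
configuration across periods amounts to running the post period with a
singleton grid.

## Relative-risk reduction

All summaries are contrasts of the fitted surface against a reference
concentration (by default the reference city's median over the fitting
period), with delta-method standard errors
$\sqrt{c' \hat V_{\beta} c}$ and 95% Wald intervals on the log scale
($z = 1.96$; the interval type is not otherwise specified in this design,
and Wald is the convention):

* `overall_cumulative()` — the exposure-response curve summing all lags,
  on 100 equally spaced exposure values over the basis range by default;
* `exposure_lag_surface()` — the full surface as a long table;
* `extreme_effects()` — per-lag RR of the 90th and 10th exposure
  percentiles against the median (type-7 empirical quantiles).

The reference identity (RR exactly 1 at the reference, with zero width)
holds by construction, not within a tolerance.

## The synthetic-data generator

Because the admissions databases this design targets are access-restricted,
the package ships a generator whose defaults emulate a Korean metropolitan
panel at desk scale; every downstream stage is tested by parameter recovery
against its known truth.

* **Pollutant**: winter-peaking annual cycle (amplitude 12 ug/m3 around a
  45 ug/m3 mean) plus AR(1) deviations (coefficient 0.7, innovation sd 8),
  truncated at 1 ug/m3. Exposure history before the panel start is padded
  with the stationary mean so day 0 has a full lag window and row counts
  are deterministic.
* **Counts**: negative binomial with $V(Y) = \phi\mu$ (size
  $\mu/(\phi-1)$, degenerating to Poisson at $\phi = 1$; default
  $\phi = 1.5$, mild overdispersion typical of daily admissions), baseline
  about 20 admissions per city-day with two annual harmonics (amplitudes
  0.15 and 0.05 on the log scale).
* **Meteorology**: five mutually independent seasonal sinusoids plus noise;
  DTR is generated as simulated daily maximum minus minimum temperature and
  is therefore non-negative by construction. The default covariate effect
  is a small temperature slope (0.006 per degree C) with the others null.
* **Truth surface**: a product family $f(x,l) = (g(x)-g(x_{\mathrm{ref}}))
  \, w(l)$ with $g$ an inverted-U quadratic peaking at 40 ug/m3 (amplitude
  0.08 log-RR, half-width 30 ug/m3) and $w$ a geometric decay (rate 0.7)
  over lags 0..14 normalized to sum to one, so the cumulative effect equals
  $g(x)-g(x_{\mathrm{ref}})$ in closed form. Baseline rates are not
  reported for the real cohorts; the defaults were chosen once for
  statistical power at desk scale, not realism.

What the generator deliberately does **not** emulate: epidemic dynamics and
holiday effects; correlation between meteorology and the pollutant (so
covariate omission cannot confound the exposure effect — recovery tests
exercise estimation, not confounding control); missing days; reporting
artefacts. Passing recovery tests therefore show the pipeline estimates
what it models, not that the model is adequate for any particular real
series.

## Problem sizes and the recovery experiment

The replicated recovery experiment (`recovery_replicate()`) simulates 3
cities over 4 years, runs the full two-stage pipeline — including the
32-mask covariate search — and scores the pooled cumulative curve against
truth. Its grid fixes the maximum lag at the truth's 14 days with 4 degrees
of freedom per dimension: a 4-df natural spline spans the
quadratic-by-geometric truth family closely, so coverage of the 95%
intervals is dominated by sampling noise rather than basis approximation
bias (with 3 df per dimension the approximation bias is already visible in
the upper exposure range). Monte-Carlo calibration over 200 replicates
gives mean pointwise coverage of about 0.93 under the default effect
surface and about 0.95 of grid points containing RR = 1 under a null
surface.

## Known limitations

* Lag-0 lag-specific effects are structurally zero (see the cross-basis
  conventions above).
* Fixed-effect pooling only; between-city heterogeneity inflates Q but is
  not propagated into the pooled intervals.
* Single-pollutant models only; PM10 and PM2.5 are never co-included, and
  gaseous pollutants are out of scope.
* Missing days fail validation by default; linear interpolation is offered
  only for gaps of at most two days behind an explicit flag.
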