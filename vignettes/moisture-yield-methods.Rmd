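---
title: "Methods: moisture indices, trends and the yield-response panel model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: moisture indices, trends and the yield-response panel model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatmoist)
```

This vignette documents the models behind `wheatmoist`, the assumptions
they carry, the tunable parameters, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the
methods literature leaves room.

## 1. The moisture index

The Standardized Precipitation Evapotranspiration Index (SPEI) expresses
the climatic water balance — precipitation minus atmospheric water demand
— in standard-normal units, per calendar month and per accumulation
scale. The chain implemented in `compute_spei()` is:

1. **PET (Thornthwaite).** Monthly potential evapotranspiration from
   monthly mean temperature and latitude only. The annual heat index is
   computed from the record's per-calendar-month mean temperatures
   (climatological normals, negatives clamped to zero); months at or
   below 0 °C evaporate nothing; above 26.5 °C the standard
   high-temperature polynomial replaces the power law; each month is
   scaled by daylength (from solar declination at the month's mid-day)
   and month length. Thornthwaite is the least data-hungry PET method
   and the conventional choice when only temperature is recorded; it
   will underestimate demand in windy or dry-air conditions, a known
   limitation that multi-site standardization largely absorbs.
2. **Water balance and aggregation.** `D_i = P_i − PET_i` (mm), then
   trailing sums over k months (`aggregate_balance()`); the first k − 1
   months are undefined. Short scales (1, 3) track soil moisture and are
   the agriculturally relevant ones; 6 and 9 months describe
   medium-term hydrological balance.
3. **Distribution fit.** Each calendar month's aggregated sample is
   fitted with a three-parameter log-logistic distribution via unbiased
   probability-weighted moments. The fit is per calendar month because
   the seasonal cycle makes the monthly samples non-exchangeable.
4. **Standardization.** The exceedance probability is mapped through the
   classical rational approximation of the normal quantile (constants
   2.515517, 0.802853, 0.010328; 1.432788, 0.189269, 0.001308). Its
   documented accuracy, ≤ 4.5e-4 absolute against an exact normal
   quantile, is asserted in the tests.

Moisture levels follow the conventional seven-class scheme, implemented
closed on the drought side: extreme drought ≤ −2, moderate drought
(−2, −1], slight drought (−1, −0.5], normal (−0.5, 0.5), slight wetting
[0.5, 1), moderate wetting [1, 2), extreme wetting ≥ 2. The printed
class tables in the source literature show touching decimal ranges
(−0.99 ~ −0.5 and so on); the half-open convention here is the one
consistent with the quantitative response table being reproduced.

### Numerical choices

- **Calibration period.** Distribution fits use all input years unless
  `calibration_years` restricts them. A ≥ 30-year record gives at least
  30 values per calendar-month fit; the fitter requires ≥ 10.
- **PWM estimator.** Unbiased (plotting-position-free) estimators of
  `E[X (1−F)^s]`. Switching to plotting-position PWMs would be a
  one-line change in `fit_loglogistic()`; on 30+ year samples the
  difference is far inside the calibration tolerance.
- **Negative L-skewness.** The log-logistic family carries positive
  L-skewness only, and a long synthetic record occasionally produces a
  calendar-month sample with slightly negative L-skewness. Such samples
  are fitted after reflection (the mirror member of the same
  generalized-logistic family) and flagged `reflected = TRUE`; the CDF
  and quantile functions undo the reflection transparently. Without the
  fallback one month in several hundred would abort the pipeline.
- **Tail clamping.** Aggregates at or below the fitted origin γ (or far
  above) are clamped to cumulative probability 1e-6 / 1 − 1e-6, bounding
  |SPEI| ≈ 4.75 rather than failing; only extreme tails are affected.
- **Completeness.** Gaps are an error naming the site and month, never
  silently imputed.

## 2. Trend tests

`mann_kendall()` implements the rank-based test with the tie-corrected
variance and the continuity-corrected normal deviate; `sens_slope()` is
the median of all pairwise slopes. Two-sided p-values throughout, with
α = 0.05 by default. Ties can occur only in values, not in time (one
value per month or year). Series of length 4–10 are accepted but
flagged `small_sample`, since the normal approximation is only asserted
beyond n = 10. Both a monthly and an annually aggregated series can be
tested — `trend_suite()` takes whatever per-site series it is given —
because the choice of aggregation is a user decision, not a property of
the test. No pre-whitening is applied; the test's size under
autocorrelated input is the user's responsibility (the type-I error is
verified at nominal level for i.i.d. input).

## 3. Yield linkage

Stages are fixed: S1 sowing/seedling (Oct–Nov), S2 over-wintering
(Dec–Feb), S3 late growth (Apr–Jun), full season (Oct–Jun). March
belongs to no stage; the gap is deliberate fidelity to the source
convention rather than a judgment that March is irrelevant. Seasons are
labeled by harvest year: October–December sit in the preceding calendar
year, which is the only labeling under which a 1979–2014 climate record
supports 1980–2014 harvests.

A stage covariate at scale k is the arithmetic mean of the k-month SPEI
values of the stage's months — e.g. `SPEI_3_S3` is the mean of the
3-month SPEI of April, May and June. The growing-season table averages
the window-ending months October–June; at scales above 1 those windows
reach before October, which is inherent to trailing-window indices.

Both yields and covariates are detrended by first differences before
Pearson correlation (two-sided t-test, n − 2 degrees of freedom; stars
at 0.05 and 0.01). Differencing removes any linear trend exactly — an
invariance the property tests assert — at the cost of one season and
some power relative to model-based detrending.

## 4. The panel model

`fit_panel()` estimates

$$Y_{i,t} = \beta_i + \alpha_1 s_{i,t} + \alpha_2 s_{i,t}^2 + \alpha_3 t + u_{i,t}$$

by LSDV: ordinary least squares on site dummies, the covariate, its
square and a linear time index t = 1, 2, … over the sorted panel years
(only differences of t matter for the slopes). Fixed effects are the
appropriate design when site intercepts may correlate with the moisture
covariate. The Durbin-Watson statistic of the within-site-ordered OLS
residuals is always computed; under the default "auto" policy, AR(1)
correction engages when DW leaves [1.5, 2.5] — the source analysis
reports only that autocorrelation "existed", so the trigger is
configurable. The correction is iterated Cochrane-Orcutt: ρ from the
pooled within-site regression of residuals on their lagged values
through the origin; quasi-differencing of response and all regressors
including the dummies (first observation per site dropped); refit;
iterate to |Δρ| < 1e-6 or 50 iterations. Nonlinear least squares with an
AR term — what commercial econometrics suites do — would be an
equivalent swappable estimator; the derived response quantities depend
only on the coefficient values. Adjusted R² is reported from the final
(transformed) regression including dummies, with the centered total sum
of squares so the dummy-saturated design does not inflate it. The mean
intercept is the unweighted mean of the β_i; per-site effects are the
raw intercepts, from which deviations are trivially recovered.

### Derived response surface

With both moisture coefficients negative the response
`r(s) = 1000 (α₁ s + α₂ s²)` kg/ha (zero at s = 0 by construction) is a
concave parabola: `optimum_spei()` returns the vertex −α₁/(2α₂),
`loss_thresholds()` the roots 0 and −α₁/α₂, and `response_table()` the
seven moisture-level intervals with the response evaluated at their
endpoints. The printed convention for the table is endpoint evaluation
even where the vertex falls inside an interval (slight drought), so the
table reports endpoint bounds as `response_lo`/`response_hi` and adds a
vertex-aware `response_max` column. Reporting precision follows the
source: responses to 1 decimal kg/ha, thresholds to 2 decimals.

## 5. The synthetic world

The generator states the world the tests live in; its defaults are fixed
and are not tuned to outcomes:

| Parameter | Default | Basis |
|---|---|---|
| Sites, latitudes | 10 sites, 31.08–34.50 °N | documented station network |
| Site annual mean temperature | 13–16 °C, south warmer | documented regional range |
| Annual precipitation | 724–1210 mm, north dry / south wet | documented regional range |
| Warming slope | 0.04–0.07 °C/yr, north → south | documented Sen-slope range |
| Seasonal temperature amplitude | 12 °C, cosine peaking in July | regional climatology; Northern-Hemisphere phase |
| Temperature noise sd | 0.8 °C/month | synthetic choice: gives realistic annual-mean scatter (~0.23 °C) |
| Monthly precipitation | gamma, shape 1.2, monsoon weights peaking Jun–Aug | synthetic choice reproducing monsoon seasonality and right-skew |
| Yield model coefficients | α₁ = −0.1592, α₂ = −0.1297, α₃ = 0.0626, ρ = 0.39, β̄ = 3.3376 | reported estimation regime, used as simulation truth |
| Yield innovation sd | 0.25 t/ha | synthetic choice (no reported magnitude); yields span ≈ 2.3–6.3 t/ha, matching the reported 2.93–5.76 t/ha scale |

AR(1) errors are independent across sites (the model specifies no
cross-site structure), and one seed drives each generator call. The
generator does **not** emulate spatial correlation between sites, daily
weather, or extreme-event statistics; a green calibration or recovery
test therefore establishes correctness of the *methods* under the
model's own assumptions, not climatological realism of any single
series, and none of the station-data-dependent numbers (per-site
correlation cells, fitted coefficient values, adjusted R²) are
reproduction targets.

## 6. Known limitations

- Thornthwaite PET ignores wind, humidity and radiation; Penman-Monteith
  or Hargreaves alternatives are out of scope.
- The response table extrapolates the quadratic beyond |SPEI| = 2 where
  panel support is thin; the unbounded rows should be read as "at least
  this loss".
- No pre-whitening in the trend tests; no clustered or robust standard
  errors, random effects, or vertex confidence intervals in the panel
  model.
- Phenological stages are fixed calendar windows, not site- or
  year-specific observations.
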