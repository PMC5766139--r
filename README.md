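# wheatmoist

Rain-fed winter wheat in humid east-Asian lowlands is limited as much by
water *excess* as by drought: the nine-month growing season (October
through June) exposes the crop to waterlogging in wet springs and to
water deficit in dry ones. `wheatmoist` is an analysis pipeline that
quantifies how annual wheat yields respond to moisture variation, using
the Standardized Precipitation Evapotranspiration Index (SPEI) as the
moisture measure. It is written for agro-climatologists and crop
modellers who want the full chain — index construction, trend testing,
correlation screening, and panel regression — as tested, reusable
functions rather than a one-off script.

## What it computes

**Multi-scalar SPEI.** For each site, monthly potential evapotranspiration
(PET) comes from the Thornthwaite temperature/daylength method; the
climatic water balance `D_i = P_i − PET_i` is summed over trailing windows
of k = 1, 3, 6, 9 months; each calendar month's aggregate sample is fitted
with a three-parameter log-logistic distribution by unbiased L-moments;
and the cumulative probability is mapped to standard-normal units, so
SPEI ≈ −2 is extreme drought and +2 extreme wetness.

**Trend detection.** The Mann-Kendall test
`S = Σ_{k<j} sgn(x_j − x_k)` with tie-corrected variance and a
continuity-corrected normal deviate, plus Sen's slope
`median{(x_j − x_k)/(j − k)}`, applied per site to temperature,
precipitation and SPEI series.

**Yield linkage.** Yields and stage-mean SPEI covariates (S1 sowing
Oct–Nov, S2 over-wintering Dec–Feb, S3 late growth Apr–Jun, and the full
season) are detrended by first differences and screened with Pearson
correlations.

**Panel model.** The quadratic fixed-effects model

```
Y_{i,t} = β_i + α₁ SPEI_{i,t} + α₂ SPEI_{i,t}² + α₃ t + u_{i,t},
u_{i,t} = ρ u_{i,t−1} + ε_{i,t}
```

is estimated by least squares with site dummies (LSDV); a Durbin-Watson
test triggers iterated Cochrane-Orcutt AR(1) correction. From the fitted
parabola the package derives the optimum moisture level
`−α₁/(2α₂)`, the yield-loss thresholds (roots of the response), the
moisture-level → yield-response table `1000 (α₁ s + α₂ s²)` kg/ha, and
decade summaries.

A synthetic-data module (`default_sites()`, `generate_climate()`,
`generate_yields()`) simulates a ten-site network on the documented
climatic gradients so that every stage is testable without external
station data.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
synthetic world (each writes its tables under `results/`). The core of
stages 1, 2 and 5 in a session:

```r
library(wheatmoist)
climate <- generate_climate(default_sites(), 1979, 36, seed = 1)
spei    <- compute_spei(climate, scales = 3)
cov     <- season_covariate(spei, "S3", 1980:2014, 3)
yields  <- generate_yields(cov, default_panel_params(), seed = 2)
fit     <- fit_panel(yields, cov)
fit
#> Fixed-effects quadratic moisture-response panel fit
#>   alpha1 (SPEI)      -0.1561 t/ha
#>   alpha2 (SPEI^2)    -0.1099 t/ha
#>   alpha3 (trend)      0.0644 t/ha per year
#>   mean intercept      3.3324 t/ha over 10 sites
#>   AR(1) rho           0.3248 (applied, 5 iteration(s))
#>   DW (OLS resid)      1.3385   adj R2 0.8169   n 350
round(optimum_spei(fit), 2)
#> [1] -0.71
```

The fit recovers the generating coefficients (α₁ = −0.1592,
α₂ = −0.1297, α₃ = 0.0626, ρ = 0.39) within single-replicate noise: the
DW statistic of 1.34 flags the AR(1) structure, the correction estimates
ρ ≈ 0.32, and the negative quadratic term places the yield optimum at
slight drought (SPEI ≈ −0.7) — wet excess costs more yield than equal
drought, the asymmetry the concave parabola encodes.

With the reported coefficient table as input, the derived response
surface is exact:

```r
ref <- list(alpha1 = -0.1592, alpha2 = -0.1297)
round(yield_response(c(2, 1, 0.5, -0.5, -1, -2), ref), 1)
#> [1] -837.2 -288.9 -112.0   47.2   29.5 -200.4
round(c(optimum_spei(ref), min(loss_thresholds(ref))), 2)
#> [1] -0.61 -1.23
```

## Acceptance script

`scripts/acceptance.R` recomputes the externally checkable quantities of
the analysis — the yield responses at the seven moisture-level interval
endpoints and the decade-mean responses, all derived by running the
package's response operations on the reported coefficient table — and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — the package: synthetic data, SPEI core, trend tests, yield
  linkage, panel model, pipeline I/O (`run_pipeline()`).
- `analysis/01_simulate.R … 05_panel.R` — the narrative workflow.
- `vignettes/moisture-yield-methods.Rmd` — model, assumptions, numerical
  choices, limitations.
- `tests/testthat/` — unit, property and acceptance tests.
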