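---
title: "Socio-environmental vulnerability mapping: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Socio-environmental vulnerability mapping: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geovuln)
```

## The problem

Geriatric depression clusters in space: elderly residents of dense,
low-rise, heterogeneous historical neighbourhoods (the "Tong Lau" building
stock of Hong Kong is the canonical example) screen positive on the
15-item Geriatric Depression Scale (GDS-15) more often than residents of
planned estates. `geovuln` implements a complete analysis chain that turns
a geocoded elderly cohort plus three raster layers (land use, vegetation
mask, building height) into (i) adjusted odds ratios for social and
built-environment risk factors, (ii) a linear *socio-environmental
vulnerability index* weighted by those odds ratios, (iii) a map of the
index at planning-unit scale, and (iv) a validation of that map against
the cohort outcome. Because the original survey data are restricted, the
package ships a synthetic-city generator that reproduces the study
conditions, so every stage is exercised end to end by code alone.

## Outcome and exposures

A subject is a **case** when GDS-15 ≥ 8, the screening cutoff recommended
for Asian elderly populations, and a control otherwise. Five binary social
indicators describe social vulnerability: older age (≥ 80 years), male,
not married, low education (elementary school or below), and living
alone. Four continuous measures describe the built environment within a
circular buffer of radius 400 m around the subject's address:

* **pct. residential** — percentage of buffer cells whose land-use class
  is residential ("private residential", "public residential", "rural
  settlement");
* **pct. vegetation** — percentage of vegetated cells;
* **avg build height** — mean building height (metres) over built cells;
* **std build height** — standard deviation of building height over built
  cells.

A cell belongs to the buffer when its *centre* lies within the radius —
the simplest unbiased rule; the package's brute-force oracle tests
enumerate every cell centre and apply the distance test directly. Buffers
are clipped at the raster edge (the denominator is the number of valid
in-extent cells) and subjects whose buffer is more than half outside the
extent are flagged. Layers are nearest-neighbour resampled to the working
resolution, which preserves class labels and heights exactly; because the
layers are piecewise constant, buffer summaries are insensitive to the
working resolution (the tests verify 10-m native against refined grids
within 1%), so analyses at the 10-m native resolution and at 1 m agree.

Two choices here were genuinely open. First, whether the height
statistics average over *built cells only* or treat unbuilt ground as 0 m:
built-cells-only matches the semantics of "building height" and produces
means near the observed ~33 m, so it is the default, with
`built_cells_only = FALSE` available. Second, the percentile
normalization of the two height measures ("normalized to 100%
percentiles") can be computed over the analytic cohort or citywide: the
model stage uses the cohort (the estimand is a cohort-level association),
while the mapping stage normalizes citywide, since the map covers areas
without subjects. Percentiles use the Hazen plotting position
`100·(rank − 0.5)/n` with average ranks for ties; it is symmetric,
bounded away from 0 and 100, and invariant under monotone transforms.

## The regression layer

Crude associations come from 2×2 tables via `OR = ad/bc` with the Woolf
interval `exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`; no continuity
correction is applied, so a zero cell is a named error rather than a
silently corrected estimate. Tables can be rebuilt from published group
sizes and percentages (`reconstruct_table()`), using round-half-to-even —
this matters because, e.g., 19.8% of 364 is 72.07.

The adjusted models are binomial logistic regressions
`logit P(case) = β₀ + β₁·older + β₂·male + … + β₁₅·smoking`, fitted by an
internally implemented IRLS (Newton scoring) engine: weights
`w = p(1 − p)`, update `β ← β + (XᵀWX)⁻¹Xᵀ(y − p)`, step-halving whenever
a step would decrease the log-likelihood (the trace is stored and tested
to be non-decreasing), convergence at `max|Δβ| < 1e-8` within 100
iterations, standard errors from the inverse observed information.
Separation is flagged as non-convergence with a warning, never reported
as a finite estimate; rank-deficient designs error naming the collinear
columns. Model 1 uses the social indicators, Model 2 the environmental
measures, Model 3 both; the six lifestyle/medical confounders (dementia,
physical activity, cardiovascular disease, respiratory disease, alcohol,
smoking) are always included. Physical activity is standardized to zero
mean and unit variance before fitting — its survey scale is arbitrary,
and standardization leaves all other odds ratios untouched. Building
heights enter as 0–100 percentiles (raw metres behind
`height_scale = "raw"`), and records with any missing model variable are
excluded (complete-case analysis, with the count logged). With one binary
predictor the engine reproduces the crude OR of the collapsed table
exactly — an algebraic identity the tests assert to 1e-10 — and on
general designs it agrees with a derivative-free likelihood grid search
and with an independent GLM implementation. No multiple-testing
correction is applied anywhere.

## The vulnerability index

Variables whose Model-3 confidence interval excludes 1 are retained, and
each weight is its adjusted OR minus 1 — the fractional increase in odds
per unit. A retained binary indicator cannot be mapped subject-wise, so
it enters the map as an area-level population percentage and its weight
is further divided by 100 (risk change per 1% of the population). With
the published Model-3 estimates (low education 1.60, pct. residential
1.01, avg height 0.98, std height 1.03) this yields

> index = 0.006·pct. low education + 0.01·pct. residential
> − 0.02·avg-height percentile + 0.03·std-height percentile.

Weights are derived from ORs rounded to two decimals by default — the
presentation precision at which published formulas are stated —
with `round_digits = NULL` for unrounded simulation work. The index is
exactly linear in every input layer and any nodata input propagates.

For the map, the environmental layers are 400-m moving-window summaries
at the mapping resolution (10 m), computed by FFT convolution with a disc
kernel — identical, cell-centre for cell-centre, to the per-subject
buffer operator, which the tests verify. The population-percentage
layers are zone-constant rasters from the planning-unit census
attributes. Zone summaries are means over valid cells, reported binned to
the nearest 0.1 — the scale unit of the published map; zones with no
valid cell (no settlement) are flagged and carry no number. Whether to
compute the index per cell and then average, or directly from zone-level
inputs, is another open choice; cell-then-aggregate is the default
because it preserves within-zone variation in the zone mean.

## Validation

The mapped index is read back at each subject's location (half-open cell
convention; subjects on nodata cells are excluded with a logged count)
and the outcome is refit on the index *alone*. The association is
reported per 0.1-point index increase, the map's scale unit:
`OR₀.₁ = exp(0.1·β)` with the CI rescaled on the coefficient — exactly
equivalent to pre-dividing the index, and tested as the identity
`OR₀.₁¹⁰ = OR₁`. Published validation of this design reports the OR per
scale unit; the per-0.1 reading is implemented and documented as such.

## What the synthetic city emulates — and what it does not

`city_config()` defaults *are* the study conditions: a 4 km × 4 km city
at 10-m resolution, 64 rectangular planning units, 4000 subjects placed
uniformly on residential cells, case prevalence calibrated to 364/3930 ≈
9.3%, control-group covariate marginals (older 9.5%, male 50.5%, not
married 28.1%, low education 65.5%, living alone 12.9%), a not-married ×
living-alone correlation of 0.55 (drawn jointly from the 2×2 cell
probabilities implied by the marginals and the phi coefficient), and a
0.35% missingness rate (≈14 of 4000 rows, matching the reported
complete-case loss). The built city is a blocky patch model: rectangular
residential estates, vegetation patches, and clustered building
footprints whose per-estate height scale is lognormal (median 26 m, log-sd
0.45) with large within-estate spread (log-sd 0.65). That height
hierarchy is what produces the strongly positive correlation (~0.8–0.9)
between buffer-average and buffer-SD of building height that the real
city exhibits (r = 0.82), because both statistics track the local height
scale. Outcomes are drawn from the true logistic model; the intercept is
recalibrated by a root find so the expected prevalence hits the target
regardless of the covariate effects. GDS-15 scores are drawn uniform 8–15
for cases and 0–7 for controls — only the dichotomy matters downstream.
The paper-style true effects for the social and environmental terms use
the published adjusted ORs; the confounders' marginals and effects are
assumptions of the generator (the source survey does not publish them)
and are exposed in the config.

The generator deliberately does **not** emulate: coastline or topography,
address geocoding error, spatial sorting of social covariates into
neighbourhoods (subjects' indicators are independent of location, and the
zone census percentages are drawn independently of the subjects), or
NDVI-derived vegetation. Passing tests therefore show that the *pipeline*
is correct and well calibrated under realistic effect sizes and spatial
autocorrelation — not that the published effect estimates themselves are
recoverable from any real city.

## Problem sizes and numerical notes

The test-suite simulations use a 4-km city (400×400 cells) with cohorts
of 3 944–4 000 for the recovery and coverage experiments (50 seeds), a
1.5-km city with 600–900 subjects for the 100-seed null-coverage check,
and 50 000 subjects for the prevalence-convergence check — sizes at which
the Monte-Carlo error of each assertion is comfortably below its
tolerance. Recovery loops evaluate subject features at the containing
10-m cell centre via the FFT moving-window rasters (≤ 7 m displacement on
a 400-m buffer); the default per-point extraction is what the brute-force
oracle checks. FFT convolution counts are rounded to the nearest integer
to remove 1e-12-level floating-point noise before division. All
randomness flows from the single config seed; generators set derived
seeds (seed + fixed offsets) so each stage is individually reproducible.

## Worked example

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(city = city_config(seed = 5)))
writeLines(res$log)
print(adjusted_ors(res$fits$model3))
print(res$weights)
print(res$validation)
```

## Known limitations

* Planar coordinates only; no CRS handling or geodesic distances.
* Rasters are in-memory matrices; city extents beyond ~10⁴ cells per side
  would need tiling.
* Wald intervals only (no profile likelihood or Firth correction), as in
  the published analysis; rare-exposure cells can make Wald coverage
  optimistic.
* The index inherits the printed two-decimal OR precision by default —
  by design, since the published formula does too.
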