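# geovuln

Socio-environmental vulnerability mapping for geriatric depression risk.

Elderly residents of dense, low-rise neighbourhoods with heterogeneous
building stock carry a measurably higher risk of depression (GDS-15 ≥ 8)
than residents of planned estates. `geovuln` is an R implementation of the
full analysis chain behind that finding, aimed at spatial epidemiologists
who have (or want to simulate) a geocoded elderly cohort plus land-use,
vegetation and building-height rasters:

1. **Buffer features** — for each subject, percentage residential area,
   percentage vegetation, and mean/SD of building height within a 400-m
   circular buffer (cells counted when their centre is within radius;
   nearest-neighbour resampling to a configurable working resolution).
2. **Risk models** — crude odds ratios from 2×2 tables with Woolf/Wald
   95% CIs, `OR = ad/bc`, `CI = exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`;
   and adjusted models fitted by an internally implemented IRLS logistic
   engine, `logit P(case) = β₀ + β₁·older + β₂·male + β₃·not married +
   β₄·low education + β₅·living alone + β₆·pct res + β₇·pct veg +
   β₈·avg-height pctile + β₉·std-height pctile + confounders`, with
   Models 1 (social), 2 (environmental) and 3 (both).
3. **Vulnerability index** — every variable whose Model-3 CI excludes 1
   is weighted by `OR − 1` (divided by 100 for binary indicators mapped
   as population percentages), giving e.g. the published form
   `0.006·pct low education + 0.01·pct residential − 0.02·avg-height
   pctile + 0.03·std-height pctile`.
4. **Mapping & validation** — the index is computed citywide at 10-m
   resolution (FFT moving-window buffers + zone-constant census layers),
   aggregated to planning units at a 0.1 scale unit, read back at
   subject locations, and validated by a univariate logistic fit
   reported per 0.1-point index increase.

A synthetic-city generator (`city_config()`, `synth_study()`) reproduces
the study conditions — ~4000 subjects, 9.3% prevalence, the published
covariate marginals and correlation structure — so the whole pipeline is
testable without the restricted survey data.

## Worked example

```r
library(geovuln)

# crude OR from a published summary row: 19.8% of 364 cases vs
# 12.9% of 3566 controls exposed (living alone)
crude_or(reconstruct_table(364, 19.8, 3566, 12.9))
#> term                         OR (95% CI)
#> exposure                     1.66 (1.26, 2.19) *

# end-to-end synthetic run
res <- run_pipeline(pipeline_config(city = city_config(seed = 5)))
writeLines(res$log)
#> simulate: n=4000 subjects, 387 cases / 3613 controls, seed=5
#> complete-case: 3990 retained, 10 removed
#> cases/controls after filtering: 386 / 3604
#> fit: model 3 loglik -1192.60, converged TRUE, n_used 3990
#> weights: not_married=+0.004, low_education=+0.0058, pct_residential=+0.01, avg_build_height_pctile=-0.02, std_build_height_pctile=+0.03
#> map: index range [-1.525, 2.887] over 64 TPUs
#> validate: OR per 0.1 = 1.114 (1.087, 1.143), n=3990

res$validation
#> Vulnerability-index validation (univariate logistic)
#> n = 3990 subjects (0 excluded on nodata cells)
#> term                         OR (95% CI)
#> index (per 0.1)              1.11 (1.09, 1.14) *
#> risk increase per 0.1-point index: 11.4%
```

Reading: with realistic (published-size) true effects, the fitted Model-3
odds ratios select low education and the three built-environment terms
(plus, in this draw, not-married) into the index; the mapped index spans
negative (protective) to positive (vulnerable) neighbourhoods; and a
0.1-point increase of the mapped index carries an 11% higher odds of
depression — significantly above 1, as the design intends.

The methods vignette (`vignettes/vulnerability-mapping.Rmd`) documents
the model, the buffer and normalization conventions, the generator's
assumptions, and known limitations.

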