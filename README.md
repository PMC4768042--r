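# orientia

Tools for measuring a population's *past orientation* from search-engine
query volumes and relating it to region-level suicide rates through
ecological panel regression.

## The scientific problem

Search queries that contain year phrases carry a temporal signature: early
in a year people search for the year just gone, and attention gradually
shifts to the year ahead. A region whose residents keep searching for the
previous year — relative to the next one — exhibits a collective
*past orientation*, and dwelling on the past (regret, rumination) is a
recognized psychological risk factor for suicide. `orientia` turns this
idea into a reproducible pipeline for epidemiologists and computational
social scientists: normalize query counts to a Trends-style 0–100 index,
form the orientation ratio per region-year, assemble a region-year panel
with socio-economic covariates, and quantify the association with suicide
rates by OLS with exhaustive information-criterion model comparison.

The core statistic, for region *i* in base year *t*, is

    PO_it = s * (I^past_it / I^future_it),      I_it = 100 * v_it / max_j v_jt

where `I^past` and `I^future` are the normalized indices of the
previous-year and next-year phrases (normalized within each year-role slice
across regions; `v` is either the raw count or the count as a share of the
region's total query volume), and the scale `s` defaults to 1. The
regression model is

    suicide_rate_it = a + b1*unemployment_it + b2*gini_it + b3*gsp_it
                        + b4*pop_growth_it + b5*PO_it + e_it

fitted by OLS on the pooled region-year panel, with model comparison by
AIC/BIC (`-2l + 2k` and `-2l + k log n`, `k` = coefficient count) over all
2^5 − 1 predictor subsets plus a stepwise check at the 1% level.

Real inputs of this kind (Trends exports, vital statistics, labor and
economic series) are not redistributable, so the package includes a seeded
synthetic generator whose defaults emulate the intended study design — 51
regions over 2004–2012 (459 region-years), seasonally patterned year-phrase
query counts, covariates with the documented moments and correlations, and
outcomes from the linear model above — making the entire pipeline testable
offline. See the vignette in `vignettes/past-orientation-pipeline.Rmd` for
the modelling choices.

## Worked example

```r
library(orientia)

cfg   <- generator_config(seed = 42)        # 51 regions x 2004-2012
panel <- simulate_recovery_panel(cfg)       # 459-row region-year panel
fit   <- ols_fit(panel, model_predictor_sets()$model4)
print(fit)
```

```
OLS fit: suicide_rate ~ unemployment + gini + gsp + pop_growth + past_orientation   (n = 459)
             term estimate    se     t      p
      (Intercept)  -12.886 3.397 -3.79 <0.001
     unemployment    0.209 0.069  3.03 0.0026
             gini   27.418 4.902  5.59 <0.001
              gsp   -4.503 0.608 -7.41 <0.001
       pop_growth    1.082 0.183  5.91 <0.001
 past_orientation    8.042 1.554  5.18 <0.001
R2 0.280  adj R2 0.272  F 35.19 (p <0.001)
logLik -1190.30  AIC 2392.6  BIC 2417.4  sigma 3.257
```

Every coefficient lands within two standard errors of its generating value
(0.265, 28.568, −4.122, 1.140, 8.501): a one-unit rise in the orientation
index is associated here with ≈8 additional suicides per 100,000. The
subset ranking shows the orientation variable earning its place — dropping
it from the full model costs ≈24 AIC points:

```r
head(as.data.frame(all_subsets(panel, model_predictor_sets()$model4)), 3)
```

```
                                            subset      aic      bic r_squared
 unemployment+gini+gsp+pop_growth+past_orientation 2392.600 2417.374 0.2797799
              gini+gsp+pop_growth+past_orientation 2399.796 2420.441 0.2652045
                  unemployment+gini+gsp+pop_growth 2416.976 2437.621 0.2371799
```

`run_pipeline(generator_config(seed = 1), "out/")` executes the whole chain
— simulate, index, panel, descriptives, the four benchmark fits, subset
ranking, stepwise trace, per-region scatter means — writing each stage as
CSV plus a manifest with file digests. A thin command-line wrapper with
per-stage subcommands is installed at `inst/scripts/orientia.R`.

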