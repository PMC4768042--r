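---
title: "Measuring past orientation from search queries and relating it to regional suicide rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring past orientation from search queries and relating it to regional suicide rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orientia)
```

## The problem and the statistic

People reveal their temporal focus in what they search for. Early in a
calendar year, queries containing the phrase for the year just gone ("2008"
searched during 2009) dominate; as the year progresses, attention shifts to
the upcoming year ("2010"). Regions differ in how strongly their residents
dwell on the past, and a persistent preference for the past — rumination,
regret, attachment to what is gone — is a recognized psychological risk
factor for suicide. `orientia` operationalizes this *past orientation* of a
region's population from search-query volumes and relates it, alongside
standard socio-economic covariates, to region-level suicide rates.

The statistic is a ratio of normalized search indices. For region $i$ and
base year $t$, let $q^{P}_{it}$ be the query volume for the previous-year
phrase and $q^{F}_{it}$ for the next-year phrase. Each is first converted to
a Trends-style index within its $(t, \text{role})$ comparison slice,

$$ I_{it} = 100 \cdot \frac{v_{it}}{\max_j v_{jt}}, $$

where $v_{it}$ is either the raw count (`mode = "counts"`) or the count
divided by the region's total query volume (`mode = "share"`, the default,
mirroring how public Trends data are shares of a region's total search
activity). The past-orientation index is then

$$ \mathrm{PO}_{it} = s \cdot \frac{I^{P}_{it}}{I^{F}_{it}}, $$

with scale $s = 1$ by default, and the future-orientation index is its
reciprocal construction, so $\mathrm{PO} \times \mathrm{FO} = s^2$ exactly.
We default to $s = 1$ because observed past-orientation values on real data
are reported on the unit scale (roughly 0.78–1.52); a percent-style variant
is available through the `scale` argument. Because the per-slice
normalizing maxima cancel in the ratio, the *ranking* of regions within a
year is identical to the ranking by the raw ratio $q^P/q^F$ — a property the
test suite checks by brute force — so the choice of normalization mode
affects interpretability, not ordering, whenever total volumes are constant
within a slice.

Two aggregation paths are supported: monthly volumes can be summed to annual
counts before normalization (the default, used by `orientation_table()`), or
normalized monthly and inspected as a seasonal profile
(`monthly_profile()`). Annual summation before normalization was chosen as
the default because the regression operates on region-years; the monthly
path exists to expose the within-year seasonality (past-phrase interest
maximal in January and declining, future-phrase interest rising to a
December peak).

## The regression model

The analysis panel has one row per region-year with the outcome (suicides
per 100,000 population) and five predictors: unemployment rate (%), Gini
coefficient (0–1), gross state product (trillions of dollars), population
growth rate (%), and the past-orientation index. The model is pooled OLS,

$$ y_{it} = \alpha + \beta_1 u_{it} + \beta_2 g_{it} + \beta_3 p_{it}
   + \beta_4 r_{it} + \beta_5 \mathrm{PO}_{it} + \varepsilon_{it}, $$

with i.i.d. Gaussian errors. The error term is treated as independent
across rows (region-years); no serial or spatial dependence is modelled. A
single pooled intercept is the default; `ols_fit(..., year_fe = TRUE)`
swaps in year fixed effects for sensitivity analysis. Standard errors are
the classical $\hat\sigma^2 (X^\top X)^{-1}$ diagonal; robust or clustered
variants are out of scope.

Model comparison uses the Gaussian log-likelihood
$\ell = -\tfrac{n}{2}(\log 2\pi + \log(\mathrm{RSS}/n) + 1)$ with
$\mathrm{AIC} = -2\ell + 2k$ and $\mathrm{BIC} = -2\ell + k \log n$, where
$k$ counts the regression coefficients including the intercept but *not*
the error variance. This convention was adopted because it reproduces the
magnitudes conventionally reported for this model family in econometric
software; `k_convention = "coef_plus_sigma"` switches to the count that
`stats::AIC()` uses on `lm` objects (the two differ by a constant 2 in AIC,
$\log n$ in BIC, and never change model rankings). Four benchmark predictor
sets are predefined (`model_predictor_sets()`): unemployment + Gini; those
plus past orientation; the four socio-economic covariates; and the full
five-predictor model. `all_subsets()` fits every non-empty subset (all
$2^p - 1$, guarded at $p \le 20$) and ranks by AIC, ties broken by BIC,
then model size, then name. `stepwise_select()` implements forward
selection with a backward purge at a single significance level
($\alpha = 0.01$ by default): the variant is deliberately simple and fully
recorded in its trace, since "stepwise at the 1% level" admits several
conventions; the variant name and alpha travel with the result.

## What the synthetic generator emulates

Real inputs of this kind (Trends exports, vital-statistics outcomes, labor
and economic series) are not redistributable, so the package carries a
seeded generator whose defaults encode the study conditions the method is
meant for: 51 regions (the US states plus DC) over 2004–2012, i.e. a
complete 459-row panel.

*Query volumes.* The generative process for counts is a modelling choice —
public Trends data reveal only normalized indices. We use Poisson counts
with a log-linear monthly trend:
$\mu^{P}_{im} = B \, s_i \, \phi \, \lambda_i \, e^{-d(m-1)}$ and
$\mu^{F}_{im} = B \, s_i \, \phi \, e^{+f(m-1)}$, with baseline volume
$B = 50{,}000$ queries/month, phrase share $\phi = 0.02$, decay and rise
rates $d = f = 0.08$ per month, a per-region size factor $s_i$ (log-normal,
sdlog 0.5 — a population proxy that makes share-mode normalization
non-trivial), and a per-region latent $\lambda_i$ (log-normal, sdlog 0.095)
multiplying the **past** phrase only. This form was chosen because it
reproduces the qualitative seasonal signature (past-phrase interest
declining within the year, future-phrase interest peaking in December),
makes the orientation statistic identifiable (the latent is recoverable up
to a per-year constant), and keeps Poisson noise small relative to the
latent variation at the default volumes. The latent sdlog matches the
coefficient of variation of the observed orientation index (SD 0.102 on a
mean of 1.071). A `deterministic` flag replaces every draw by its
expectation, making outputs exact functions of the configuration — the
basis of the byte-reproducibility contract.

*Covariates.* The five predictors are drawn jointly multivariate normal
with the documented means and SDs (unemployment 6.309/2.285, Gini
0.607/0.035, GSP 0.281/0.341, population growth 0.899/0.887, orientation
placeholder 1.071/0.102) and the documented 5×5 correlation structure, then
truncated: Gini clipped into (0, 1), the positive-by-nature variables
floored at 0.01. One consequence deserves emphasis: a normal with mean
0.281 and SD 0.341 puts about a fifth of its mass below zero, so flooring
GSP shifts its realized mean to ≈0.32 and shrinks its SD to ≈0.28. This is
inherent to emulating a right-skewed positive variable with a truncated
normal; correlations survive (all pairs within ±0.02 at n = 10,000), and
coefficient recovery is unaffected because outcomes are generated from the
*truncated* values. The moment-convergence tests therefore check the four
variables whose floors essentially never bind.

*Outcomes.* Suicide rates follow the linear model with generating
coefficients $(\alpha, \beta_1, \ldots, \beta_5) =
(-14.623,\ 0.265,\ 28.568,\ -4.122,\ 1.140,\ 8.501)$ and residual SD
$3.779\sqrt{1 - 0.324} \approx 3.107$, derived so that the synthetic
panel's total outcome variance ($\approx 3.78^2$) and full-model
$R^2$ ($\approx 0.32$) match the marginal figures the coefficients were
calibrated against — a consistency we verified algebraically from the
covariate moments before adopting it. Outcomes are not clipped at zero by
default (keeping the linear model exact); a `clip` flag exists for
display-realistic rates.

*Two routes from config to panel.* `simulate_recovery_panel()` uses the
multivariate-normal orientation placeholder directly — the clean test bed
for parameter recovery, since the generating coefficients then apply to the
exact predictor values. `simulate_study()` (and `run_pipeline()`) instead
compute past orientation from the simulated volumes through the full index
pipeline and generate outcomes from *that* value, so the fifth predictor in
the end-to-end panel genuinely drives the outcome. In the end-to-end route
the orientation column is independent of the socio-economic covariates
(the latents are separate draws), whereas the placeholder route carries the
documented weak cross-correlations; neither route emulates serial
correlation within regions, spatial dependence, or the right-skewness of
real GSP — so green tests certify the machinery and its statistical
calibration, not those features of real data.

A master seed spawns fixed per-component sub-streams (latents, sizes,
volumes, covariates, outcomes), so regenerating one component never
perturbs another, and equal seeds reproduce every table exactly.

## Numerical and degenerate-input choices

- Index normalization computes the ratio before scaling by 100, so the
  slice maximum is exactly 100 in floating point; ties at the maximum all
  receive 100. An all-zero slice is an error (the index is undefined), as
  are negative counts.
- Correlations are clamped into $[-1, 1]$ to absorb 1-ulp overshoot;
  p-values use the exact t transform on $n-2$ degrees of freedom,
  two-sided (reported significance markers on real data are thresholds;
  two-sided is the documented convention here).
- Sample SDs use the $n - 1$ denominator throughout.
- A zero-residual (saturated) fit reports infinite likelihood, criteria of
  $-\infty$ and a `perfect_fit` flag rather than NaNs; stepwise selection
  terminates when the current model is saturated, and candidates whose
  augmented model cannot be fit (exact collinearity) simply never enter.
- Rank deficiency in `ols_fit()` is an error naming the dependent columns;
  inside `all_subsets()` it annotates the affected subset's row instead of
  aborting the enumeration, and inside `run_pipeline()` an unfittable
  benchmark model is recorded in its output table so toy-scale runs
  complete.
- `build_panel()` is strict by default (a complete regions × years grid,
  duplicate keys fatal) because the intended design is a balanced panel;
  permissive mode drops incomplete rows with one logged message each.
- In deterministic mode the run manifest omits the wall-clock timestamp so
  that two runs of the same configuration are byte-identical, which the
  test suite verifies file by file.

## Problem sizes used by the checks

The packaged checks run at the study scale where that is what is being
certified and at reduced scale where only a property is: panel completeness
and coefficient recovery use the full 459-row design (recovery judged
within two estimated standard errors of the generating value — at this
sample size the orientation coefficient's SE is ≈1.5, so single-panel
estimates legitimately scatter); the AIC/BIC improvement direction uses 100
replicate panels; coverage and bias use 200 replicates; pure-noise stepwise
behaviour uses 200 replicates at n = 200; Monte-Carlo checks of the
seasonal count trends use 500 replicates of a 3-region, 1-year
configuration; moment convergence uses n = 10,000 covariate draws.

## Known limitations

Ecological inference: the unit is the region-year, and conclusions apply to
populations, not individuals. The OLS errors are treated as exchangeable
across region-years, which understates uncertainty if regional shocks
persist across years. The generator's count model is one plausible
mechanism consistent with the published seasonal pattern, not an estimate
of the true query-generating process. And the orientation index inherits
the idiosyncrasies of Trends-style normalization — in particular, share
mode depends on the total-volume proxy, which real Trends exports do not
reveal directly.
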