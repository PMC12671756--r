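---
title: "Methods: heatwave metrics and beta regression for kelp canopy data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heatwave metrics and beta regression for kelp canopy data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpwave)
```

## The scientific setting

Floating canopy kelps are surveyed once a year, as hectares of canopy per
shoreline zone, while sea-surface temperature (SST) is available daily.
To ask whether a marine heatwave explains canopy loss and recovery, the
year of temperature exposure attributed to a survey must precede it:
kelpwave uses the September–August "water year" ending in the survey
year, so the 2014 exposure window runs from September 2013 to August
2014. Within each window three summaries are computed per zone:

* **warmest-month mean SST** (°C) — a thermal-maximum proxy; monthly
  means of daily SST, maximum across the twelve months of the window,
  ties broken by the earliest month;
* **maximum monthly SSTA** (°C) — anomaly magnitude; daily anomalies
  against a day-of-year climatology, averaged by calendar month, maximum
  across months;
* **days with SSTA > 0 °C** (count) — anomaly duration / accumulated
  exposure; a strict inequality, so a day exactly on the climatology does
  not count, and missing days are simply not counted.

These three metrics operationalize three non-exclusive hypotheses —
thermal maxima, anomaly magnitude, and accumulated warm exposure — whose
relative support can be compared by AIC within each sub-region.

## Climatology and anomalies

The climatology is the mean SST per day of year over user-chosen
reference years, pooled over a centered window of `2h + 1` days
(`smoothing_halfwidth` `h = 15` by default, the conventional 31-day
window for daily SST climatologies; `h = 0` gives raw day-of-year means).
February 29 is folded onto day 59, so every year maps onto 365 slots. A
pre-computed climatology table can be supplied instead of the builder,
because operational SST products ship their own climatologies whose
construction details differ; the builder exists so the pipeline is
self-contained.

Numerical note: each slot is computed with `mean()` over the pooled
window observations rather than a ratio of accumulated sums. R's `mean()`
accumulates in extended precision, so a window of identical values
averages to exactly that value and a series compared to its own
climatology has anomalies of exactly zero — which matters because the
duration metric counts strict sign exceedances.

Missing data are handled permissively but loudly: slots with no reference
observations become `NA` with a warning, months with no days are flagged
missing, a window with under 80% day coverage is logged, and a zone-year
whose window cannot support the metrics is dropped with a logged reason
rather than failing the whole table. Zones close enough to share an SST
grid cell are handled by a many-to-one `zone_cells` mapping; all zones of
a cell receive identical metrics.

## Canopy statistics

The pre-heatwave baseline per unit is the mean ± sample s.d. (n−1) over
2011–2013 — three years chosen as the consistently surveyed, non-heatwave
reference — and needs at least two observed years. Loss is reported as
the percent drop from the baseline mean to the minimum over 2014–2016.
A unit *declines* in the first year at/after the onset (default 2014)
below `mean − 1 s.d.` and *recovers* in the first later year back at or
above that threshold. The one-sided rule was chosen because recovery is a
return from below; a symmetric "within one s.d." variant is available via
`symmetric = TRUE` for users who want overshoot excluded. A subtlety
worth knowing: recovery timing is only monotone in the threshold when the
decline year is held fixed — a tighter threshold can also move the
decline earlier and thereby legitimately produce an earlier recovery —
so the package's property tests condition on a common decline year.

For regression, each zone-species series is scaled by its maximum over
the analysis period, giving a response in (0, 1]; exact 0 and 1 are
replaced by 0.01 and 0.99 so the beta likelihood is defined. Scaling is
per zone because each regression observation is one zone-year, and the
fold-difference and loss statistics are reported at sub-region totals
(species summed) because that is the scale at which annual totals are
tracked. Reported tables round fold differences to one decimal and losses
to integer percent; full precision is kept internally.

## The beta regression

With `y ∈ (0,1)`, `kelpbeta()` fits

$$y_i \sim \mathrm{Beta}(\mu_i \phi_i,\ (1-\mu_i)\phi_i), \qquad
g(\mu_i) = x_i^\top \beta, \qquad \log \phi_i = z_i^\top \gamma,$$

so `E(y) = μ` and `Var(y) = μ(1−μ)/(1+φ)`. The default mean link is the
Cauchy quantile `g(μ) = tan(π(μ − ½))`: its heavy tails tolerate
responses that sit near the scaled maximum in most years and crash in
heatwave years, where a logit or probit link would force extreme linear
predictors. The precision submodel uses a log link; `y ~ x` fixes
`φ` constant, `y ~ x | x` lets it vary with the covariate.

Estimation choices:

* **Optimizer** — BFGS on the negative log-likelihood with the analytic
  score (the `digamma`-based gradient of the beta likelihood), relative
  tolerance 1e-12, at most 500 iterations. Invalid parameter points
  return a large penalty rather than `-Inf` so line searches recover;
  within the score, `μ` and `φ` are clamped at ±1e-12 / 1e12 only to keep
  the gradient finite at the boundary.
* **Starting values** — ordinary least squares of `g(y)` on the mean
  design for `β`; method-of-moments `φ` from the OLS residual variance
  (`φ₀ = mean(μ₀(1−μ₀))/σ̂² − 1`, floored at 1.1).
* **Uncertainty** — observed information from a numerical Hessian at the
  optimum; Wald `z` statistics against the standard normal, matching
  common beta-regression summaries. A fit is flagged non-converged when
  the optimizer fails or the Hessian is not positive definite, and the
  comparison functions refuse flagged fits.
* **Pseudo-R²** — the squared Pearson correlation between the fitted
  linear predictor and `g(y)` with the same link as the fit, defined as 0
  for intercept-only models. This is the documented default of the
  standard beta-regression implementation; other variants exist but were
  not layered on.
* **Model comparison** — AIC with `k = length(β) + length(γ)`; fits
  within 1 AIC unit of the minimum are flagged co-best rather than
  ranked, since differences below 1 are conventionally not interpreted.
  The precision-misspecification check is the likelihood-ratio statistic
  `2(ℓ_full − ℓ_reduced)` clamped at zero against χ² with the parameter
  difference as df; identical specifications are a degenerate comparison
  and return statistic 0, p 1.

The covariate is standardized (z-scored within sub-region) before
fitting in the pipeline, so slopes are comparable across metrics with
different units and the optimizer works at unit scale.

## Diagnostics

* **Breusch–Pagan** operates on an ordinary linear fit of the same
  formula (the test is defined for OLS residuals, not the beta
  likelihood); the studentized (Koenker) form `n·R²` of the auxiliary
  regression is the default because it is robust to non-normality, with
  the classical form behind `studentized = FALSE`. Both variants are
  exposed because published analyses do not always state which was used.
* **Moran's I** uses inverse Euclidean distance between zone centroids as
  weights, zero diagonal, *no row standardization* — the weights enter
  exactly as supplied — with the analytic randomization variance and a
  two-sided normal p-value. Any consistent planar projection of the
  centroids is acceptable since only relative distances matter. For n = 3
  the statistic is defined but the randomization variance is not, so the
  p-value is `NA` with a warning; the pipeline skips sub-regions with
  fewer than 3 zones outright.
* **Wilcoxon rank-sum** reports the Mann–Whitney pairs statistic (a > b
  pairs, ties one half), exact by enumeration when the smaller group has
  at most 10 observations and no ties, otherwise normal approximation
  with tie and continuity corrections.
* **Levene** is a one-way ANOVA on absolute deviations from the group
  center; median centering (Brown–Forsythe) is the default, as in common
  ecological practice, with classical mean centering selectable. Median
  centering is known to be slightly conservative in small groups, which
  the calibration checks reflect.

## What the synthetic data emulates — and what it does not

`simulate_sst()` builds `mean + amplitude·cos(2π(doy − peak)/365)` plus
stationary AR(1) noise (lag-one correlation 0.8, stationary s.d. as
given) plus boxcar heatwave events of constant intensity. Defaults
(mean 10 °C, amplitude ~3 °C, peak day 227 ≈ mid-August) imitate
temperate Northeast-Pacific nearshore SST. `simulate_canopy()` draws the
scaled response from the same Cauchy-link beta model the package fits,
with the covariate z-scored within sub-region so effect sizes are
unit-comparable; `make_fixture()` assembles six sub-regions × ten zones
with one SST cell per sub-region (mirroring how real zones share 5-km
grid cells), daily SST 1989–2021, and a heatwave block starting March
2014 whose duration (270 → 1020 days) and intensity (1.2 → 3.2 °C)
escalate inland.

Passing tests on these data demonstrate that the estimators recover known
generating mechanisms — not that real kelp dynamics are captured. The
generator has no nutrient dynamics, no spatially correlated noise fields,
no species interactions, no observation error in the aerial surveys, and
its canopy depends on a single temperature metric at a time, whereas the
real analysis found all metrics weakly and jointly informative. The
published regression effect sizes (pseudo-R² of roughly 0.05–0.18) are
therefore *not* reproduction targets: reproducing them would require the
actual survey and satellite records. What the end-to-end fixture checks
is directional: longer/stronger injected anomalies delay recovery, fitted
slopes are negative, and recovery trails the coastal sub-regions inland.
Because the recovery threshold sits one baseline s.d. below the mean, and
the fixture's baseline variability is modest, individual sub-regions can
straddle the threshold by chance; robust checks therefore compare
coastal and inland groups rather than every adjacent pair.

## Problem sizes

The test-suite and acceptance computations use sizes chosen to make Monte
Carlo noise small relative to the quantities checked while staying
comfortably interactive: 200 replicates at n = 500 for slope bias and
Wald coverage, 2000/1000 simulations for the Breusch–Pagan and Levene
size checks, 500 constant-precision simulations at n = 150 for the
uniformity of the LR p-value, and a two-stage grid (0.1 then 0.003
spacing) for the 12-point likelihood oracle. The synthetic study region
spans 33 years of daily SST over 6 cells and 60 zones.

## Known limitations

* The maximum-monthly-anomaly metric averages daily anomalies by calendar
  month of the window; products that interpolate their own monthly
  climatologies may differ in the third decimal.
* Beta regression here is plain maximum likelihood — no bias-corrected or
  bias-reduced estimators, no mixed effects, no temporal autocorrelation;
  zone-years are pooled without year effects, matching one-point-per-
  zone-year analyses.
* Recovery classification depends on a short three-year baseline; with a
  small baseline s.d. the threshold is strict, and single noisy years can
  flip the recovery year.
* Moran's I is the analytic randomization test, not a permutation test,
  and no spatial correction is applied to the regressions (the design
  assumes the diagnostic is a check, not a fix).
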