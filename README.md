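# kelpwave

Tools for relating annual floating-kelp canopy area to marine-heatwave
exposure along a coastal-to-estuarine gradient, built around the workflow
used to study bull kelp (*Nereocystis luetkeana*) and giant kelp
(*Macrocystis pyrifera*) responses to the 2014–2016 Northeast Pacific
heatwave: annual temperature metrics from daily sea-surface temperature
(SST), canopy baseline/loss/recovery statistics from aerial-survey tables,
and beta regressions of scaled canopy area on temperature.

## What it computes

**Temperature metrics.** From a tidy daily SST table per zone (or shared
5-km grid cell), the package builds a day-of-year climatology over
reference years (centered smoothing window, default 31 days), derives
anomaly series `SSTA(t) = SST(t) − clim(doy(t))`, and summarizes each
September–August "water year" preceding a canopy survey with three
metrics: the mean SST of the warmest month, the maximum monthly mean SSTA,
and the count of days with SSTA > 0 °C.

**Canopy response.** From annual canopy areas (hectares) by zone,
sub-region and species: the pre-heatwave baseline mean ± sample s.d.
(2011–2013 by default), percent difference from baseline, fold difference
max/min, maximum loss in the heatwave window, the decline/recovery years
(recovery = first year back at or above mean − 1 s.d.), and scaling of each
zone series to the fraction of its maximum (exact 0/1 replaced by
0.01/0.99) for use as a regression response.

**The model.** The response `y ∈ (0,1)` is beta-distributed in the
mean–precision parameterization,

    y ~ Beta(μφ, (1−μ)φ),  E(y) = μ,  Var(y) = μ(1−μ)/(1+φ),

with mean link `g(μ) = tan(π(μ − ½))` (the standard Cauchy quantile;
logit and probit are available) and, optionally, a log-linear precision
submodel `log φ = z'γ` (`y ~ x | x`). `kelpbeta()` maximizes the
likelihood with BFGS and the analytic score, and ships the usual S3
methods (`summary`, `coef`, `vcov`, `logLik`/`AIC`, `predict`,
`residuals`, `simulate`, `plot`). Model comparison uses AIC with models
within 1 unit flagged co-best; the pseudo-R² is the squared correlation of
the fitted linear predictor with the link-transformed response.

**Diagnostics.** Breusch–Pagan (studentized by default, via `lmtest`),
a likelihood-ratio test for precision misspecification, Moran's I on raw
inverse-distance weights between zone centroids, the Wilcoxon rank-sum
test, and Levene's test (median-centered by default).

**Synthetic data.** `simulate_sst()` (seasonal cosine + AR(1) noise +
boxcar heatwave events), `simulate_canopy()` (Beta draws from a known
Cauchy-link relationship) and `make_fixture()` (a six-sub-region miniature
study area with an escalating 2014–2016 heatwave) provide ground truth for
every stage, so the whole pipeline is testable without any downloads.

## Worked example

Fold differences from the published sub-region minima/maxima (stored as a
text table under `inst/extdata/`):

```r
library(kelpwave)
tab <- read.csv(system.file("extdata", "table1_printed.csv", package = "kelpwave"))
data.frame(sub_region = tab$sub_region,
           fold = fold_difference(tab$min_ha, tab$max_ha))
#>                sub_region fold
#> 1              Open Coast  2.1
#> 2          Western Strait  2.1
#> 3          Eastern Strait  3.6
#> 4 Smith & Minor Island AR  3.4
#> 5       Cypress Island AR  1.6
#> 6         Cherry Point AR 13.0
```

The ratio of largest to smallest annual canopy ranges from about 2 on the
open coast to 13-fold at Cherry Point — the most variable sub-region.

An end-to-end run on the synthetic study region, then one fitted model:

```r
fx  <- make_fixture(seed = 1)
cfg <- run_config(reference_years = fx$reference_years)
res <- run_pipeline(cfg, fx$sst, fx$canopy, zones = fx$zones,
                    zone_cells = fx$zone_cells)

d <- merge(res$scaled, res$metrics, by = c("zone_id", "survey_year"))
d <- d[d$sub_region == "Cherry Point AR", ]
d$x <- as.numeric(scale(d$warmest_month_mean_sst))
summary(kelpbeta(scaled ~ x, d))
#> Beta regression (cauchy mean link)
#>
#> Mean submodel:
#>             Estimate Std. Error z value Pr(>|z|)
#> (Intercept)   1.9284     0.2046   9.426   <2e-16 ***
#> x            -1.8313     0.1906  -9.607   <2e-16 ***
#>
#> Precision submodel (log link):
#>                   Estimate Std. Error z value Pr(>|z|)
#> (phi)_(Intercept)    2.636      0.156    16.9   <2e-16 ***
#>
#> logLik: 93.6910  AIC: -181.3820  pseudo-R2: 0.2721  n: 80
```

The negative slope says warmer warmest-months coincide with lower scaled
canopy in that sub-region (here the fixture's generating slope is negative
by construction, and `res$recovery` shows the inland sub-regions
recovering later than the coastal ones, mirroring the injected gradient in
heatwave duration and intensity).

A thin command-line front end over the same functions lives at
`inst/cli/kelpwave.R` (subcommands `metrics`, `response`, `regress`,
`diagnose`, `simulate`, `run`).

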