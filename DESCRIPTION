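Package: kelpwave
Title: Marine Heatwave Temperature Metrics and Kelp Canopy Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate annual floating-kelp canopy area to marine
    heatwave exposure. Builds day-of-year sea-surface-temperature (SST)
    climatologies and anomaly series from daily records, summarizes three
    annual exposure metrics over September-August windows (warmest-month
    mean SST, maximum monthly SST anomaly, and count of days with positive
    anomaly), computes pre-heatwave baselines, loss and recovery statistics
    from annual canopy surveys, and fits beta regression models with a
    Cauchy mean link (optionally with covariate-dependent precision) by
    maximum likelihood, together with model comparison via AIC,
    heteroscedasticity and precision-misspecification tests, and Moran's I
    spatial diagnostics. Includes a synthetic-data generator with known
    ground truth so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lmtest,
    jsonlite,
    yaml
Suggests:
    ape,
    car,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
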