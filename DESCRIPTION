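Package: pm25ens
Title: Ensemble Spatiotemporal Estimation of PM2.5 Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating daily fine particulate matter (PM2.5)
    concentrations from sparse monitoring networks. Fits bagged
    generalized additive models on log concentrations with temporal basis
    functions extracted by singular value decomposition, aggregates
    ensemble members by weights proportional to the square of their
    out-of-bag R-squared, and reports a weighted standard deviation as a
    prediction uncertainty. Daily spatial autocorrelation left in the
    ensemble residuals is captured by empirical variogram estimation,
    variogram-family selection by leave-one-station-out cross-validation,
    and ordinary kriging, with block averaging for regional means. A
    synthetic-data generator emulating a provincial 96-station network
    supports end-to-end testing, and six model scenarios with k-fold and
    out-of-bag validation support model comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
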