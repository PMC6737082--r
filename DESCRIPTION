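Package: turtleindex
Title: Relative-Abundance Indices for Oceanic-Stage Sea Turtles from Observer Line Transects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives annual relative-abundance indices of oceanic-stage juvenile
    loggerhead sea turtles from opportunistic fishery-observer line transects.
    Implements quality-control filtering of transects (length/speed plausibility,
    Beaufort sea state, kernel-density spatial core), smearing of heaped angle and
    distance measurements, binned multiple-covariate distance-sampling detection
    functions (hazard-rate and half-normal keys with adjustments, AIC selection,
    chi-square goodness of fit), a one-stage zero-inflated Poisson generalized
    additive model of counts with a log effective-area offset, nonparametric
    bootstrap standard errors and percentile confidence intervals for the
    two-stage estimator, and lagged cross-correlation of the index against an
    annual nest-count series. A synthetic observer-program generator with known
    truth supports testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    mgcv,
    geosphere,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
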