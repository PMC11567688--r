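Package: mmtrend
Title: Temporal Trends in Minimum Mortality Temperature from Daily
    Time-Series Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage analysis of temporal change in the minimum mortality
    temperature (MMT) and its percentile (MMTP) across communities and
    countries. Stage one fits per-community, per-subperiod quasi-Poisson
    distributed lag non-linear models (DLNM) of daily all-cause deaths on
    daily mean temperature, reduces the cross-basis coefficients to the
    lag-cumulative exposure-response, and estimates the MMT with Monte-Carlo
    uncertainty. Stage two pools the subperiod estimates with a two-level
    (country, community) mixed-effects meta-regression with known sampling
    variances, providing BLUPs, stratified fits, heterogeneity tests and
    average-temperature adjustment. A synthetic-data generator produces
    multi-country daily mortality and temperature series with known
    ground-truth MMT trends for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
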