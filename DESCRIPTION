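Package: medpql
Title: Predicted Quarantine Lengths for Mediterranean Fruit Fly Outbreaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating how long a Mediterranean fruit fly
    (Ceratitis capitata) quarantine must extend past the last fly detection.
    Implements the regulatory three-generation degree-day calculation
    (single-sine and hourly-summation methods) and a stochastic,
    stage-structured agent-based simulation of population elimination under
    sterile insect technique and control mortality, swept over biological
    parameter uncertainty with Latin hypercube sampling. Includes hourly
    temperature series cleaning (outlier removal, gap filling, hourly
    resampling), a synthetic hourly climate generator for testing and
    demonstration, day-of-year climatological normals without smoothing,
    and site-level comparison statistics (variance decomposition, latitude
    regression, nearest-station matching, paired method comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    grDevices,
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2,
    lhs,
    geosphere,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
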