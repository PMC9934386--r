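Package: vegamove
Title: Migration Phenology and Movement Analysis for GPS-Tracked Gulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for multi-year GPS tracking data from
    long-distance migrant gulls: fix-level filtering and deployment bookkeeping,
    spherical geodesy with time-regularized resampling and an equal-area
    projection, solar-elevation diel classification, standardized two-hour bout
    analysis (rates of travel, flight altitudes, migration bouts), absolute
    displacement migration phenology with individual and population migratory
    windows, dynamic time warping route repeatability with permutation
    inference, Mantel migratory connectivity with bootstrap confidence
    intervals, and seasonal kernel utilization distributions. Includes a
    seed-reproducible synthetic track generator emulating Arctic
    breeding/temperate wintering annual cycles so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    lubridate,
    readr,
    geosphere,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
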