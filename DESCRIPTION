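Package: camtrapcoex
Title: Co-Occurrence and Activity Analysis for Camera-Trap Surveys of
    Carnivore Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing camera-trap surveys of sympatric carnivore
    communities: filtering photographs into independent detection events,
    survey-effort accounting and monthly relative activity indices,
    solar-anchored diel activity estimation with circular kernel densities
    and coefficients of overlap (with smoothed-bootstrap confidence
    intervals), selection-ratio and randomization tests of diel time-budget
    use versus availability, and two-species occupancy models with a
    species interaction factor and AIC model selection. A synthetic survey
    generator with known occupancy, co-occurrence, diel and seasonal
    structure supports testing and power analysis without field data.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
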