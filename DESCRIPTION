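Package: eyecover
Title: Effective Cataract Surgical Coverage from Population-Based Eye Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cataract surgical coverage (CSC) and effective cataract
    surgical coverage (eCSC) from RAAB-style population survey data of adults
    aged 50 years and older. Classifies participants into indicator numerators
    and denominators at configurable visual-acuity thresholds, post-stratifies
    estimates to the age-sex structure of the survey-area population, computes
    cluster-adjusted standard errors for the two-stage cluster design, derives
    the relative quality gap between CSC and eCSC, selects and pools estimates
    across surveys within a country, and runs random-effects meta-analysis of
    male-female coverage differences. A synthetic survey generator with known
    ground truth supports validation of the whole pipeline without access to
    restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
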