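Package: crowdcal
Title: Crowdsourced Calorie Estimation: Accuracy, Bias and Wisdom of the Crowd
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for crowdsourced calorie estimation quizzes:
    error and discrete-accuracy metrics, participant and response quality
    filters, wisdom-of-the-crowd consensus estimates with bootstrap
    crowd-size comparison tests, expert versus crowd comparison,
    mixed-effects bias regressions (energy density, reference objects,
    demographics, BMI-by-density interaction), and food-by-food error
    correlation networks with cluster extraction. Includes a synthetic
    respondent cohort generator with the statistical structure these
    analyses assume, so every stage is testable without raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
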