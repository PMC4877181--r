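Package: alcotax
Title: State Alcohol Tax Incidence Microsimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models who would pay how much more for alcohol (product plus
    tax) under hypothetical state alcohol tax increases. Classifies survey
    respondents by drinking pattern from past-30-day consumption questions,
    builds state-level price, tax, and total cost per standard drink
    (including regression interpolation of taxes for monopoly "control"
    states), applies tax scenarios with a price-elasticity consumption
    response, and aggregates survey-weighted per-capita and aggregate net
    costs by drinking pattern, income, employment, and race/ethnicity. A
    synthetic-data generator calibrated to published national survey
    marginals stands in for restricted microdata so the full pipeline runs
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
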