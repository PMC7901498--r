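Package: opicohort
Title: Phenotyping and Mortality Validation for Opioid-Use Cohorts in
    Primary Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies patients with a history of illicit opioid use in
    primary-care electronic health record extracts using curated clinical
    and prescription codelists, including a demographic screen that
    separates opioid-agonist-therapy products from analgesic
    methadone/buprenorphine products. Assembles a follow-up cohort with
    explicit entry/exit rules, characterises it at baseline, and validates
    it by indirect standardisation of mortality (standardised and crude
    mortality rates with exact Poisson confidence intervals, computed
    over a day-level Lexis expansion of person-time) and by cross-checking
    against hospital admissions with opioid-disorder diagnoses. Ships a
    synthetic EHR generator with known ground truth so the whole pipeline
    is testable without access to licence-restricted data.
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
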