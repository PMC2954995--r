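Package: nutricohort
Title: Endpoint Analysis of Daily Parent-Reported Symptom Checklists in
    Naturalistic Micronutrient Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal databases of daily
    parent-reported symptom checklists from children taking a broad-spectrum
    micronutrient formula, where families report mood (16-item, 0-48) and
    ADHD (8-item, first three items scored, 0-9) severity scales together
    with psychiatric medication doses.  Implements eligibility filtering
    (age window, minimum reporting-day rule), baseline and monthly-binned
    last-observation-carried-forward severity endpoints, a dose-normalised
    Medication Index anchored to each client's personal maximum dose,
    paired and Welch two-sample statistics with Cohen's d, responder
    classification at strict percent-reduction thresholds, subgroup splits,
    and dropout analyses.  A synthetic cohort generator with a latent
    proportional-effect mixture, intermittent reporting, month-of-dropout
    structure, and improvement-coupled medication tapering supports
    testing and parameter-recovery studies in the absence of the original
    proprietary database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
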