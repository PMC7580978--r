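Package: triplef
Title: Triple-F Classification of Bacteriuria and Urinary Tract Infection in
    Emergency Department Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of hospitalized emergency-department
    encounters with bacteriuria. Implements quantitative urine-culture
    significance filtering, blood-culture contaminant adjudication,
    urine/blood accordance assessment, the three-criterion "triple F"
    (fever/failure/focus) score, and the five-way partition of encounters
    into bacteremic, probable and possible urinary tract infection with
    systemic involvement, urocystitis and asymptomatic bacteriuria.
    Includes diagnostic-test-accuracy statistics (sensitivity, specificity,
    predictive values with exact binomial confidence intervals, Youden-index
    cutoff selection, Cohen's kappa), antimicrobial-stewardship impact
    estimates, a constraint-built deterministic fixture cohort, and a seeded
    stochastic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
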