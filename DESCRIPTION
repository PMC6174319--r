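Package: flossr
Title: Family Longevity Selection Score Computation and Validation Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scoring familial longevity in genealogical lifespan data.
    Builds sex- and birth-cohort-specific life tables conditional on survival to
    age 40 from individual-level pedigree records, computes the Family Longevity
    Selection Score (FLoSS) for sibships, selects exceptional families by score
    threshold, and validates the selection by comparing left-truncated
    Kaplan-Meier survival of exceptional and ordinary groups at a cross-sectional
    study year and among their offspring. Includes a Gompertz-gamma shared
    frailty pedigree simulator so every stage can be exercised without access to
    restricted population databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
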