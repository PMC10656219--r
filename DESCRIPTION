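Package: dietvalidr
Title: Validation Analytics for AI-Based Dietary Assessment Food Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for validating automated (computer-vision) and
    semiautomated (user-corrected) food logging against weighed food
    records. Classifies logged foods against served foods through the
    hierarchical 8-digit FNDDS coding system (exact match, far match,
    intrusion, omission), tabulates match frequencies with exact paired
    tests of proportions, computes meal- and item-level energy percent
    error with within-bounds concordance, performs Bland-Altman agreement
    analysis with proportional-bias testing and calibration regression,
    and scores the CSUQ and USS usability instruments. Includes a seeded
    synthetic study generator emulating a laboratory meal-provision
    validation design, and a reporting pipeline that renders the full
    analysis as CSV/JSON bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
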