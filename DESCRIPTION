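Package: vetgrade
Title: Completeness Grading and Quality Analysis of Veterinary Adverse
    Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with spontaneous veterinary adverse-event
    (AE) reports: a structured report data model with validity checking
    against the four minimum reporting criteria, an adapted vigiGrade
    completeness scorer (ten multiplicative element scores with 10/30/50
    percent penalties and a well-documented threshold of 0.8),
    VeDDRA/ATCvet terminology coding and SPC expectedness classification,
    corpus-level descriptive statistics and route comparisons (exact
    Wilcoxon signed-rank, chi-squared and Fisher tests), XML batch export
    for gateway-style submission, and a seeded synthetic report generator
    with closed-form expected scores for end-to-end testing without real
    pharmacovigilance data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
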