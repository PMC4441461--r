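Package: ahpbr
Title: Analytic Hierarchy Process for Benefit-Risk Decision Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete Analytic Hierarchy Process (AHP) toolkit for
    multi-criteria benefit-risk assessment: decision-hierarchy modelling
    and validation, pairwise-comparison judgment matrices with
    principal-eigenvector priority derivation and consistency
    diagnostics, ideal and distributive synthesis with
    relative-difference significance tables, geometric-mean group
    aggregation across expert panels, weight-override sensitivity
    scenarios, and a synthetic expert-cohort generator for parameter
    recovery studies. Ships a worked clinical example ranking add-on
    pharmacotherapies to metformin for type 2 diabetes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
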