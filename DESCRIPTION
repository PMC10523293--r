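Package: hinstab
Title: Multi-Source Detection of Housing Instability in Electronic Health Records
Version: 0.1.0
Authors@R: person("Daniel", "Reyes", email = "dreyes@example.org", role = c("aut", "cre"))
Description: Identifies evidence of housing instability in electronic health
    record (EHR) data for substance-use-disorder populations by combining three
    channels: structured ICD-10-CM diagnosis codes (Z59*), semi-structured
    patient addresses matched against a curated directory of community housing
    resources, and unstructured clinical notes processed with negation-aware
    keyword matching, shelter-name matching, and dictionary named-entity
    recognition with knowledgebase linking. Includes evidence fusion with Venn
    partitioning of the identification sets, census-tract aggregation under
    codes-only versus all-sources modes, inter-rater concordance statistics
    (Fleiss' kappa, chi-squared with adjusted standardized residuals, Fisher's
    exact test), a stratified adjudication sampler, and a seeded synthetic EHR
    generator with planted ground truth so the whole pipeline is testable
    without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stringi,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
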