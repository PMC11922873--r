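Package: faersignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection in
    FDA Adverse Event Reporting System (FAERS) quarterly data, built around
    the comparison of levodopa/benserazide and levodopa/carbidopa motor
    complication profiles in Parkinson's disease. Reads FAERS-dialect
    dollar-delimited ASCII tables, deduplicates case versions, screens
    reports through a configurable cascade (suspect-drug match, oral route,
    indication and exclusion filters, system-organ-class restriction), maps
    reaction preferred terms to composite motor-complication endpoints, and
    computes three disproportionality statistics per drug-event pair: the
    reporting odds ratio with Wald intervals, the Bayesian confidence
    propagation neural network information component, and the multi-item
    gamma-Poisson shrinker empirical Bayes geometric mean, combined into a
    joint signal criterion. Includes a synthetic FAERS-dialect data
    generator with planted associations of known strength so every stage is
    testable end to end without a database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
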