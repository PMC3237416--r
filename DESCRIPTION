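Package: adrcat
Title: Adverse Drug Reaction Causality Assessment Tools and Inter-Rater
    Agreement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Executable scoring engines for two adverse drug reaction (ADR)
    causality assessment instruments: the Naranjo ten-item weighted
    questionnaire and the Liverpool decision-tree tool, the latter encoded
    as a validated, data-driven flowchart document. Includes the
    inter-rater reliability battery used in multi-rater causality studies
    (pairwise linear weighted kappa with asymptotic confidence intervals,
    exact-agreement and extreme-disagreement percentages, multi-rater
    Fleiss kappa, Altman interpretation bands), collation of per-assessor
    category counts, instrument comparison, and a seeded simulator of
    rater panels with latent true categories and ordinal misclassification
    noise so the whole pipeline can be exercised without clinical data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
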