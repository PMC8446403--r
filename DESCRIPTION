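Package: cognet
Title: Longitudinal Cognitive Change, Brain Connectomes, and Endocrine
    Predictors in Two-Group Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for prospective two-group (patient versus
    control) studies of cognitive change. Implements standardized
    regression-based (SRB) change scores with practice-effect adjustment and
    classification of clinically significant change, Fisher exact comparison
    of decline/improvement rates with Haldane-corrected odds ratios and Woolf
    confidence intervals, graph-theoretic analysis of structural brain
    connectomes (small-worldness against degree-preserving null models,
    efficiency, node degree and betweenness, summarized as area under the
    curve over a network-density range, with FDR-corrected node-level tests),
    calculated free testosterone from mass-action binding equilibria, and
    regression models linking hormonal, genetic, and network change to
    cognitive change. Includes a synthetic cohort generator that emulates the
    full data structure so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
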