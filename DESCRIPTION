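Package: kinsig
Title: Kinase-Signature Subtyping and Survival-Guided Signature Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering and validating kinase-abundance signatures
    that stratify tumours into treatment-sensitive and treatment-resistant
    subgroups. Provides a synthetic-data generator for cell-line kinase panels
    and patient survival cohorts, cross-platform harmonisation (minimum-value
    imputation, per-cohort z-scoring, PCA cohort diagnostics), a bootstrap
    ensemble of random-forest classifiers with majority-vote subgroup calls and
    averaged feature importance, survival machinery (Kaplan-Meier, log-rank,
    Cox proportional hazards, treatment-benefit criteria, multiplicative and
    additive interaction, proportional-hazards and linearity checks, gated
    baseline-comparison tests), an importance-ranked forward feature-selection
    loop driven by per-subgroup treatment-benefit criteria, and two-group
    Cox sample-size planning with a simulation verifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
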