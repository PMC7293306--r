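Package: adrisk
Title: Patient-Tailored Adverse Drug Reaction Risk Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks and aggregates the adverse drug reactions (ADRs) a
    patient on a multi-drug regimen is at risk of, combining a drug-to-ADR
    frequency knowledge base (SIDER-like) with a patient-tailored severity
    model trained on spontaneous-report data (FAERS-like). Per-ADR
    frequency scores use the at-least-one-event probability of a Poisson
    binomial over the queried drugs; severity is the ensemble-averaged
    probability of hospitalization or death from five single-hidden-layer
    neural network classifiers; ADRs passing a severity threshold are
    ranked and aggregated into Total, System Organ Class, hospitalization
    and mortality risk scores. Includes a fully specified synthetic-data
    generator with a Bayes-probability oracle, hold-out validation metrics
    (ROC AUC, Brier score, reliability curves) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    nnet,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
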