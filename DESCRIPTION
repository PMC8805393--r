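Package: nntoc
Title: Personalised Drug Recommendation for Cognitive Decline in Dementia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counterfactual per-drug prediction of cognitive scale scores
    (MMSE/MoCA) from longitudinal electronic health record visit tables,
    with an argmax treatment-of-choice rule over the four anti-dementia
    drugs (donepezil, galantamine, rivastigmine, memantine), concordance
    grouping, decline-trajectory comparison and permutation feature
    importance. Includes a synthetic longitudinal cohort simulator with
    planted per-patient drug-response heterogeneity so the whole pipeline
    is testable end to end, a hand-written two-layer LSTM score predictor
    with fully connected front-end, ridge/random-forest/1D-CNN baselines,
    minority-drug oversampling and multitask (two-scale) training with
    missing-label masking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
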