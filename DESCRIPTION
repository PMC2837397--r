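Package: mechsim
Title: Similarity of Enzyme Reactions and Catalytic Mechanisms from Bond Changes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the similarity of enzyme-catalysed reactions at two
    levels: overall reactions, represented as sets of elementary bond changes
    and compared with Tanimoto coefficients, and stepwise catalytic
    mechanisms, compared by dynamic-programming alignment (Needleman-Wunsch
    with unpenalised gaps, Smith-Waterman for local blocks) of per-step
    bond-change similarities. Handles reaction reversibility by bond-change
    inversion and step-order reversal, curated circular permutation of
    mechanistic steps, removal of spontaneous steps and stereochemistry-only
    records, and size normalisation by the maximum attainable score. Includes
    background-based significance machinery (confusion matrices,
    precision/recall/F-measure, Matthews correlation, empirical significance
    cutoffs, enrichment factors, ROC curves with trapezium-rule AUC) and a
    seeded synthetic-reaction generator for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
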