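Package: dsynet
Title: Mechanism-Driven Prediction and Interpretation of Drug
    Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the synergy of anti-cancer drug combinations from
    network-propagated drug-target profiles and cell-line gene dependency
    or expression features. Drug targets are diffused over a weighted
    protein-protein interaction network by random walk with restart; the
    resulting genome-wide drug-effect profiles, together with cell-line
    feature vectors on a shared gene panel, feed a self-attention
    transformer regression model without positional encoding. Includes
    cold-start evaluation protocols (leave-combination, leave-cell-line
    and leave-drug-out splits driven by affinity-propagation clustering),
    pair-swap training augmentation, regression and classification
    metrics, per-cell-line z-score prioritisation of untested pairs, and
    Shapley-attribution-driven gene set enrichment (SA-GSEA) for
    per-prediction interpretation. A synthetic-data generator with a
    planted synergy mechanism makes the whole pipeline testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    pROC,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
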