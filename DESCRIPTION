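Package: hdnnmir
Title: Hybrid Neural-Network Decision Trees for Imbalanced pre-miRNA
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classification of precursor-microRNA hairpins against
    pseudo-hairpins in extremely class-imbalanced feature tables using a
    hybrid model (H-DNN): a binary decision tree whose every internal
    node embeds a small dense feed-forward network trained by
    backpropagation, with samples routed by the argmax of the node
    network's two output units and splits accepted by weighted Gini
    impurity decrease. Includes deterministic imbalance-ratio
    undersampling that reproduces the benchmark count ladders of the
    five genome datasets (animal, plant, human, arabidopsis, virus),
    feature screening (correlation matrix, ANOVA-F select-above-mean,
    recursive feature elimination with cross-validation), macro-averaged
    confusion-matrix metrics, an imbalance-ratio sweep driver, and a
    synthetic correlated-Gaussian feature-table generator so the whole
    pipeline is testable without the genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
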