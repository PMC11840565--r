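Package: gpsign
Title: Contrastive Signed Graph Diffusion Networks for Gene-Phenotype
    Association Sign Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a gene up- or down-regulates a phenotype from
    a sparse signed bipartite graph of TWAS-derived associations.  The model
    combines signed random walk with restart diffusion (with balance
    attenuation factors), stochastic edge-mask augmentation into four graph
    views, sign-specific graph attention encoders with cross-view fusion,
    and a joint objective of inter-/intra-view contrastive losses and a
    three-class (up/none/down) cross-entropy.  Includes a latent-factor
    synthetic-data generator, BLAST tabular similarity readers, a projection
    perceptron for genes lacking TWAS associations, evaluation metrics, and
    robustness/ablation experiment harnesses.  Gradients are computed with a
    small built-in reverse-mode tape over dense matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
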