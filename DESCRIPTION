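Package: gsclassify
Title: Neural-Network Classifiers for Genomic Selection of Phenotypic Classes
Version: 0.1.0
Authors@R: person("gsclassify", "maintainers", email = "gsclassify@example.org",
    role = c("aut", "cre"))
Description: Classifies breeding candidates into percentile-defined phenotypic
    classes (upper/middle/lower tails of a continuous trait) from genome-wide
    marker data. Implements a probabilistic neural network (Gaussian-kernel
    Parzen/Bayes classifier with softmax posteriors and AUC-driven bandwidth
    selection) and a multilayer perceptron (tansig layers, scaled conjugate
    gradient training, early stopping, replicate ensembling), together with
    percentile trait discretization, target-class ROC-AUC and average-precision
    evaluation, a stratified cross-validation harness with partition-index
    (PINDX) matrices, a synthetic genotype-phenotype simulator with additive
    and epistatic architecture, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
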