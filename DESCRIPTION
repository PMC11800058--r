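Package: sparseMET
Title: Sparse-Testing Allocation Designs and Genomic Prediction for
    Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and evaluating sparse-testing strategies in
    multi-environment plant breeding trials. Provides synthetic generation of
    marker and plot-level phenotype data with configurable variance components,
    SNP quality control and genomic relationship matrices, per-environment
    mixed-model analysis (REML) yielding genotype BLUPs and entry-mean
    heritability, Bayesian kernel prediction models with main genomic effects
    and reaction-norm genotype-by-environment interaction (Hadamard-product
    covariance), construction of non-overlapping/overlapping (NOL/OL)
    allocation designs, and CV1/CV2 cross-validation by within-environment
    predictive ability and mean squared error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
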