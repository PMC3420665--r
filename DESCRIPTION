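Package: rvreg
Title: Regularized Multiple Regression Tests for Rare-Variant Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level association tests between rare genetic variants and a
    continuous trait using regularized multiple regression: ridge regression,
    principal components regression, partial least squares, sparse partial
    least squares and the LASSO, each optionally augmented with pooled
    rare-allele count predictors over a lattice of minor-allele-frequency
    thresholds. Model size and penalty parameters are chosen by information
    criteria (AIC, BIC, GIC), and significance is assessed by permutation of
    the phenotype with all selection steps repeated inside every permutation.
    Includes the Madsen-Browning weighted-sum test, the variable-threshold
    burden test and a sequence kernel association statistic as comparators, a
    synthetic genotype/phenotype simulator emulating Sanger-sequenced genes,
    and a power / type-I-error evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
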