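Package: idesc
Title: Zero-Inflated Negative Binomial Mixed Models for Multi-Subject
    Single-Cell Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cell-type-specific differential expression between two groups
    of subjects in droplet-based single-cell RNA-seq UMI data. Each gene is
    modelled with a zero-inflated negative binomial mixed model carrying
    subject-level random intercepts in both the count and the dropout
    component, with sequencing depth as an offset and a pooled LOESS curve
    supplying gene-level baseline dropout rates. The group effect (log fold
    change) is tested with a Wald statistic on the Laplace-approximate
    marginal likelihood. Includes a simulation engine for multi-subject UMI
    counts with configurable capture efficiency and ground-truth labels,
    plus evaluation utilities: permutation-based empirical type I error,
    sensitivity, specificity, AUC, Fisher overlap tests, Jaccard indices
    and per-cell effect coefficients.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
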