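Package: methylIDOL
Title: Reference-Based Whole-Blood DNA Methylation Deconvolution with
    IDOL Library Optimization
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates leukocyte cell-type proportions from whole-blood
    DNA methylation beta-value matrices by reference-based deconvolution.
    Builds discriminating probe libraries for six leukocyte subtypes
    (Neu, Mono, Bcell, CD4T, CD8T, NK) either by rank-ordered t-statistic
    selection or by IDOL, an iterative probabilistic search over a
    candidate pool that maximizes deconvolution accuracy on training
    mixtures with known composition. Provides three deconvolution
    back-ends (constrained projection / quadratic programming, robust
    partial correlation, and nu-support-vector regression), the
    evaluation statistics used to compare them (R-squared, RMSE,
    Bland-Altman limits of agreement, paired t-tests, Bartlett variance
    homogeneity, immune cell ratios, genomic-context chi-squared), and a
    seeded simulator of reference methylomes and Dirichlet artificial
    mixtures so the full selection-deconvolution-evaluation loop can be
    exercised without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    quadprog,
    MASS,
    e1071,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    genefilter,
    pracma,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
biocViews: DNAMethylation, Epigenetics, MethylationArray,
    ImmunoOncology, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
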