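Package: mrnm
Title: Whole-Genome Reaction Norm Models for Genotype-Covariate
    Correlation and Interaction
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variance-component reaction norm models for whole-genome
    analyses of gene-environment interplay. Fits univariate reaction norm
    models (RNM) in which genetic and residual effects are random
    regressions on a continuous covariate, and their bivariate extension
    (MRNM) that models the trait and the covariate jointly so
    genotype-covariate correlation can be disentangled from
    genotype-covariate interaction. Includes an average-information REML
    engine with likelihood-ratio tests, stratified comparison estimators
    (RR-GREML, GCI-GREML), a genomic-relationship-matrix toolkit with
    PLINK and GCTA file support, a generative simulator for
    genotype-covariate and residual-covariate correlation/interaction
    designs, and simulation experiments quantifying type-I error, power
    and the residual-variance inflation of standard additive models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
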