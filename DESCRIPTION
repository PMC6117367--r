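Package: phebridge
Title: Genetically Predicted Biomarkers and Phenome-Wide Association Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links quantitative biomarkers measured in one genotyped cohort to
    clinical diagnoses ascertained in a second genotyped cohort. A Bayesian
    sparse linear mixed model fitted by Markov chain Monte Carlo produces
    per-SNP weights for a biomarker; the weights are aligned to a target
    cohort's alleles and projected into standardized genetically predicted
    biomarker scores; a phecode-based phenome-wide association study with
    Bonferroni and Benjamini-Hochberg selection, positive-control evaluation,
    skewness diagnostics, stratified models and cross-cohort direction
    concordance establishes the biomarker's clinical associations. Includes a
    synthetic-cohort simulator (genotypes, biomarkers with controlled genetic
    architecture, liability-coupled diagnoses, covariates) so the whole
    pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
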