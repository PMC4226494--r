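Package: emlrt
Title: Expectation-Maximization Likelihood-Ratio Tests for Association at
    Imputed Genetic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative-trait association testing at imputed genetic
    variants that models imputation uncertainty explicitly. Implements
    likelihood-ratio tests fitted by an expectation-maximization algorithm
    for a mixture-of-regressions model, taking either posterior genotype
    probabilities (EM-LRT-Prob) or imputed dosages (EM-LRT-Dose, via
    conditional sampling of genotype probabilities given dosage) as input,
    together with the standard Dosage regression test and the
    simplex-maximized Mixture method as baselines. Includes a hierarchical
    simulator of genotype probabilities, dosages, true genotypes and traits
    calibrated to minor allele frequency and imputation quality R-squared,
    Monte-Carlo drivers for type I error, power, concordance and
    reconstruction-error studies, readers for VCF (DS/GP) and MaCH-style
    dosage/probability files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
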