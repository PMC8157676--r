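Package: wppa
Title: Genomic-Window GWAS by Bayesian Whole-Genome Regression with
    Window Posterior Probabilities of Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Window-based genome-wide association analysis using
    single-trait BayesC-pi whole-genome regression and the window
    posterior probability of association (WPPA). Windows are built
    either by physical span (e.g. 1 Mb) or by fixed SNP count, and the
    WPPA exceedance threshold can be a constant, 1/N, or the
    window-specific value p_w/p that corrects the excess of spurious
    signals arising on genotype panels with heterogeneous SNP density.
    Includes an EMMAX-style frequentist windowed chi-square comparator,
    a synthetic genotype/phenotype simulator with SNP-density hotspots
    and local linkage disequilibrium, phenotype-permutation null
    diagnostics, and partial-AUC (pAUC5) power evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
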