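Package: coupledmm
Title: Coupled Mixed Models for Joint GWAS Analysis of Two Independently
    Collected Data Sets
Version: 0.1.0
Authors@R:
    person("CMM", "Maintainers", email = "maintainers@coupledmm.org",
           role = c("aut", "cre"))
Description: Joint genetic association analysis of two independently
    collected genome-wide association studies (GWAS) with different
    phenotypes.  Implements a coupled sparse mixed model that infers the
    unobserved cross-study phenotypes, corrects confounding from
    population stratification and from study-specific collection
    artifacts (batch effects), and estimates per-phenotype sparse effect
    vectors with an ADMM consensus solver.  Includes PLINK BED/BIM/FAM
    input, kinship construction, variance-component estimation under the
    P3D (population parameters previously determined) convention,
    hyperparameter selection by binary search on the queried number of
    SNPs with a five-fold cross-validation fallback, a synthetic
    paired-study generator with Balding-Nichols population structure, and
    the univariate / merged-data / joint-lasso baseline panel with ROC
    evaluation for the recovery of SNPs associated with both phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
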