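Package: protwas
Title: Proteome-Wide Association Studies from pQTL Prediction Models and
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("protwas", "developers", email = "protwas@example.org",
           role = c("aut", "cre"))
Description: Builds and validates genetic prediction models of plasma
    protein abundance from cis and trans SNPs (top1, LASSO, elastic net
    and BLUP/ridge learners with cross-validation), and tests genetically
    predicted protein levels against disease GWAS summary statistics with
    an LD-reference-based Z statistic in the TWAS/FUSION style.  Includes
    per-SNP quality control (MAF, imputation info, missingness,
    Hardy-Weinberg exact test, strand-ambiguity), covariate adjustment and
    rank-based inverse normal transformation of protein levels, allele
    harmonization against summary statistics, Bonferroni reporting, and a
    synthetic-data module that emulates a two-cohort pQTL study with
    planted genetic architecture for end-to-end testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
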