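Package: gwamakit
Title: Liability-Scale GWAS Meta-Analysis, Heritability and Polygenic Prediction Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for case-control genome-wide association studies of complex
    traits under the liability-threshold model: synthetic cohort simulation
    with sex-specific prevalence and gene-environment interaction, N-weighted
    multivariate meta-analysis of summary statistics with heterogeneity tests,
    LD clumping and stepwise conditional selection of independent signals,
    LD score regression heritability and genetic correlation (including
    chromosome X estimators and the liability-scale transform), approximate
    Bayesian computation for comparing gene-environment interaction models,
    two-sample Mendelian randomization (IVW, Egger, Steiger filtering), and
    polygenic-score risk prediction with interaction models, cross-validated
    classification metrics and 5-year landmark labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
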