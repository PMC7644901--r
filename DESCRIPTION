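Package: grsmr
Title: Genetic Risk Scores and Two-Sample Mendelian Randomization for
    Leukocyte Telomere Length and Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds weighted, standardized genetic risk scores (GRS) for
    leukocyte telomere length from a panel of 17 GWAS index variants,
    performs genotype quality control (call rate, minor allele frequency,
    exact Hardy-Weinberg test), fits two-stage logistic and Cox
    proportional-hazards GRS association models with Benjamini-Hochberg
    false discovery rate control, harmonizes exposure and outcome GWAS
    summary statistics, and runs a two-sample Mendelian randomization
    estimator suite (inverse-variance weighted, MR-Egger, weighted median,
    profile maximum likelihood) with Cochran's Q, leave-one-out and
    MR-PRESSO sensitivity analyses. Includes synthetic-cohort generators
    and Monte-Carlo power harnesses for case-control and Weibull survival
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
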