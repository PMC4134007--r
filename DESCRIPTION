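Package: phewascan
Title: Phenome-Wide Association Scans from Electronic Health Record Billing Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for phenome-wide association studies
    (PheWAS) on electronic-health-record cohorts. Converts ICD-9 billing events
    into phecode case/control/excluded status with exclusion ranges and the
    two-distinct-days case rule, performs genotype quality control (call rate,
    minor allele frequency, imputation info, identity-by-descent relatedness
    pruning), cleans and averages BMI measurements, runs covariate- and
    BMI-adjusted additive-model logistic scans of SNPs across the phenome,
    pools cohorts with fixed-effects inverse-variance meta-analysis, and
    corrects for correlated multiple testing (Bonferroni, Benjamini-Hochberg,
    and the simpleM effective number of tests). Includes a synthetic two-cohort
    generator that plants BMI-mediated and direct pleiotropic SNP effects with
    a machine-readable truth table, so the full pipeline is testable without
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
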