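Package: sumtwas
Title: Transcriptome-Wide Association Testing from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Summary-statistic transcriptome-wide association analysis
    (TWAS): trains cis expression-prediction weights on a reference panel
    by cross-validated penalized regression, imputes the expression-trait
    association z-score from GWAS summary statistics with linkage-
    disequilibrium adjustment, and calls significant genes per tissue under
    Bonferroni and Benjamini-Hochberg control. Includes a synthetic-data
    generator covering the eight causal scenarios relating genotype,
    expression and trait, so the whole pipeline can be exercised and
    calibrated without individual-level study data, plus packaged reference
    tables from a published multi-tissue Alzheimer's disease TWAS for
    consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
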