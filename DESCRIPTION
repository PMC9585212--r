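Package: diffgwas
Title: Age-Stratified GWAS with Correlation-Corrected Differential Effect Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting genetic variants whose per-allele effects on a
    quantitative trait differ between age groups. A cohort is split into age
    quartiles, a covariate-adjusted linear-regression association scan is run
    within each stratum, the least-correlated pair of strata is selected by the
    Spearman correlation of their effect sizes, and per-variant differences in
    effect size are tested with a correlation-corrected t-statistic. Includes
    variant quality control (call rate, minor allele frequency, an exact
    Hardy-Weinberg equilibrium test), greedy LD clumping of genome-wide
    significant results into lead loci, Manhattan/QQ plot tables, readers and
    writers for VCF genotypes and PLINK-style phenotype and summary-statistic
    tables, and a synthetic-cohort generator with age-varying allelic effects
    for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
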