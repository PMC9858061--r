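Package: blupgwas
Title: Multi-SNP Mixed-Model Genome-Wide Association via SNP-BLUP Ridge Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome association analysis for binarised disease phenotypes
    using a mixed linear model that fits additive effects of all SNPs
    simultaneously (SNP-BLUP, a generalized ridge regression solved through
    Henderson's mixed-model equations) with fixed variance components, Wald
    testing against the standard normal and Bonferroni family-wise error
    control. Includes the standard pre-model steps: variant quality control
    (bi-allelic, call-rate, Hardy-Weinberg exact test and minor-allele-frequency
    filters), binary phenotype encoding from a multi-category cohort table with
    age and sex covariates, a conventional covariate-adjusted single-SNP
    baseline scan for comparison, reporting utilities (top hits, Manhattan-plot
    export, consequence-class summaries, per-gene hit lists) and a
    liability-threshold synthetic cohort generator with linkage-disequilibrium
    block genotype simulation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
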