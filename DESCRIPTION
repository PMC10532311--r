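Package: famseg
Title: Family-Based Exome Co-Segregation Filtering and Genotype-Stratified
    Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for family-based candidate-variant discovery from
    whole-exome sequencing data under a dominant inheritance model.
    Partitions pedigree members into cases and controls on quantitative
    coagulation traits (FVIII:C, VWF:Ag), applies site- and genotype-level
    VCF quality control, retains variants heterozygous in all cases and
    reference-homozygous in all controls at 100% call rate, summarizes
    survivors (allele-frequency class, region span, gene and consequence
    counts), and tests genotype-stratified expression differences with
    Tukey-fence outlier exclusion, a Shapiro-Wilk normality gate, and
    Mann-Whitney or Student tests, including 2^-ddCt qPCR relative
    quantitation for small family samples. A seeded simulator generates
    family VCFs with planted co-segregating variants among single-rule
    decoys, plus genotype-linked expression cohorts, for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
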