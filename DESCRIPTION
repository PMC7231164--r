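Package: sgselect
Title: Single-Generation Selection Scans for SNP Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects allele frequency shifts caused by a single generation of
    viability selection between two samples drawn from one panmictic gene
    pool. Implements a Monte-Carlo test for per-locus allele frequency
    differences against a beta-binomial sampling null, a forward simulator of
    one-generation viability selection for power analysis against Fisher's
    exact test, SNP quality filters (missingness, minor allele frequency,
    exact Hardy-Weinberg test, allele read-depth balance), Weir-Cockerham
    F_ST and genotype PCA, fitness-proxy phenotypes (relative condition
    factor, standardized length), polygenic scores of habitat-favored alleles
    with genotype-by-environment ANCOVA threshold sweeps, kernel-density
    survival-probability surfaces over outlier genotype space, and a
    synthetic cohort generator emulating a larval baseline with two
    post-selection juvenile groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    pracma,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
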