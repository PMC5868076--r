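Package: rrgwas
Title: Eigendecomposition-Accelerated Longitudinal GWAS with Random
    Regression Test-Day Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association analysis of longitudinal (test-day)
    phenotypes with a random regression model. The phenotypic covariance
    implied by time-varying additive genetic and permanent environmental
    effects is diagonalized once by eigendecomposition, after which every
    SNP's time-dependent effect is tested by weighted least squares with a
    Wald chi-squared statistic. Includes genotype quality control, the
    VanRaden genomic relationship matrix, LD pruning for the effective
    number of tests, EM/AI-REML estimation of random regression variance
    components, time-dependent variance and SNP-effect curves, and a
    simulation framework for type-I error and power studies with
    half-sib family structure and unbalanced test-day schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
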