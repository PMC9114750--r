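Package: snpmeta
Title: Case-Control SNP Meta-Analysis with Genetic-Model Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for case-control meta-analysis of a biallelic SNP from
    per-study genotype counts: the five classical genetic-model contrasts
    (allelic, heterozygote, homozygote, dominant, recessive), per-study odds
    ratios with Woolf variances, Hardy-Weinberg equilibrium screening of
    control genotypes, Mantel-Haenszel and inverse-variance fixed-effect
    pooling, DerSimonian-Laird random-effects pooling with Cochran's Q and
    I-squared, Egger regression and Begg-Mazumdar rank-correlation tests for
    funnel-plot asymmetry, univariable random-effects meta-regression over
    study-level covariates, allele-based power calculation, and a seeded
    generator of synthetic genotype-count meta-datasets with known truth.
    Ships a transcription of an 87-study cancer-susceptibility roster for the
    CTLA-4 rs231775 A/G polymorphism together with its subgroup taxonomy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, metafor, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
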