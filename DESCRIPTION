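Package: mitoconverge
Title: Convergent Evolution Analysis for Mitonuclear Hybrid Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse highly replicated experimental evolution of
    yeast mitonuclear hybrids (cybrids). Provides depth-of-coverage callers
    for aneuploidies and copy-number variants, a pileup-based SNV caller
    with ancestral subtraction, mitochondrial coding-fraction estimation,
    mutational-profile construction with Bray-Curtis dissimilarity and
    nonmetric multidimensional scaling, joint chi-squared / mutual-information
    locus-specificity scoring, modified Gompertz growth-curve fitting with
    factorial ANOVA and Tukey post hoc tests, competition-assay selection
    coefficient estimation, and a synthetic-cohort generator that emulates a
    7-genotype x 2-environment x 96-replicate design with full ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
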