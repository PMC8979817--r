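Package: methylphase
Title: Mutation-Specific DNA Hypermethylation Analysis from Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for calling mutation-specific DNA hypermethylation in
    tumor cohorts from whole-genome bisulfite sequencing: a beta-binomial
    Wald test for differentially methylated CpGs with method-of-moments
    dispersion shrinkage, CpG-anchored region segmentation, two-stage
    group-specificity calling, 5-hydroxymethylation estimation from paired
    oxidative bisulfite data, chromatin-state and enhancer annotation with
    a permutation null for region-set overlap, rank-curve superenhancer
    calling, and loop-anchor linking of enhancer regions to target-gene
    expression percentiles. Includes a seeded synthetic cohort generator
    with ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
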