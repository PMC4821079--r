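Package: pleiomap
Title: Cross-Phenotype GWAS Overlap, Polygenic Scoring, and Shared-Locus Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Four-stage cross-phenotype analysis of genome-wide association
    summary statistics: quantification of excess overlap of association
    signals between two traits (greedy LD pruning, cutoff-stratified Fisher
    exact tests with false discovery rate correction and a permutation null,
    effect-direction concordance), tiered polygenic risk scoring of an
    independent case/control cohort with covariate-adjusted logistic
    regression, a windowed cross-phenotype spatial mapping scan for genomic
    regions where the two traits' association profiles covary (thresholded
    against a circular-rotation permutation null), and cross-query of known
    genome-wide significant lead variants with Bonferroni correction. Includes
    a synthetic-data module that generates LD-structured reference panels,
    two-trait summary statistics with a configurable shared genetic
    architecture, and liability-threshold case/control cohorts, so every
    stage is testable without consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
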