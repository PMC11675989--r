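Package: dogfear
Title: Behavioral Genetics of Dogs from Commercial Breeding Kennels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for SNP-based behavioral
    genetics in multi-breed dog cohorts: PLINK 1 binary genotype I/O,
    marker quality control and LD pruning, method-of-moments inbreeding
    coefficients with F-test-gated two-population comparisons,
    varimax-rotated principal-component construction of fear phenotypes
    (social fear, non-social fear, startle response), fixed-effect
    phenotype adjustment, AI-REML SNP heritability on a genomic
    relationship matrix, kinship-corrected linear mixed-model association
    with Wald tests and genomic-control diagnostics, gene-window
    annotation of associated loci, and count-based and effect-weighted
    genetic risk scores. A synthetic multi-breed cohort generator with
    known ground truth (breed differentiation, within-breed inbreeding,
    linkage disequilibrium, causal variants at a target heritability)
    makes every stage testable without access to primary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
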