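Package: domscan
Title: Domestication Population-Genomic Scans for Small Resequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the population-genomic analysis of small resequencing
    cohorts of domesticated perennials, built around the avocado three-group
    (Mexican, Lowland, Guatemalan) study design. Implements site- and
    sample-level genotype QC, ancestry-threshold classification of accessions
    from admixture Q-matrices, windowed nucleotide diversity and
    Weir-Cockerham Fst, a composite-likelihood-ratio selective-sweep scan with
    loess smoothing, permutation tests for shared gene sets, genic
    hemizygosity calling from structural-variant overlap with coding
    sequence, and cross-coalescence-rate split-time estimation from
    MSMC2-style rate curves. A structured-coalescent cohort simulator with
    machine-readable ground truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
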