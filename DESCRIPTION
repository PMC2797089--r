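Package: insulatR
Title: Statistical Analysis of Insulator Protein Binding Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of multi-factor insulator
    protein binding maps: single-linkage clustering of binding sites into
    combination classes, permutation-based positional and pairwise
    enrichment statistics with empirical p-values, hidden Markov model
    segmentation of broad histone-mark domains with boundary statistics,
    chromatin signal meta-profiles around binding sites, position weight
    matrix instance scanning with exact p-value thresholds and
    hypergeometric enrichment, and a synthetic-genome generator that
    plants known co-binding, enrichment and domain structure so every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
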