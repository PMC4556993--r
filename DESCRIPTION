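Package: mirburst
Title: Evidence-Based microRNA Discovery, Authenticity Validation and
    Duplication Analysis from Small-RNA Read Stacks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers microRNA precursors from small-RNA sequencing read
    stacks mapped to a genome, validates candidate authenticity with hairpin
    folding stability against dinucleotide-shuffle null models, processing
    precision of read ends, and biogenesis-knockdown response, classifies
    conserved versus lineage-specific microRNAs by seed-region homology,
    analyses cross-species mature-sequence variation, calls tissue-specific
    expression, and scans genomic flanks for local duplication events with
    Karlin-Altschul E-values. Ships a synthetic-data generator that plants
    hairpin precursors, tandem duplicate families, a mutated sister-species
    genome, tissue-biased libraries and knockdown count tables with full
    ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
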