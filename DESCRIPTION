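Package: promoterEvo
Title: Predicting Promoter Evolution in a Transcriptionally Rewired Bacteriophage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting and analysing the evolution of RNA-polymerase
    promoter specificity in bacteriophage T7 forced to use an engineered
    polymerase. Enumerates the promoter-motif genotype space between a
    wild-type and an engineered promoter triplet, builds single-step
    prediction matrices and greedy trajectory graphs from measured in vitro
    transcription activities, counts accessible (monotonically increasing)
    mutational paths, simulates serial-passage phage evolution over a
    multi-promoter genome with mutation, duplication, bottleneck transfer and
    sequencing sampling, and scores observed promoter changes from population
    sequencing as predicted or unanticipated. Includes seeded synthetic-data
    generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, Transcription, Software
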