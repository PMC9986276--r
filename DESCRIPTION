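Package: remotif
Title: Enhancer Classification and Attribution-Based Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs labelled active and non-active enhancer sequence sets
    from open-chromatin and histone-mark peak intervals and a genome, trains a
    small one-dimensional convolutional network to separate the two classes,
    explains its predictions with Integrated Gradients, aggregates
    high-attribution seqlets into signed position weight matrices, and vets the
    resulting motifs with information-content trimming, a similarity search
    against a known-motif database, enrichment and co-occurrence statistics,
    and an expression-based transcription-factor filter. A synthetic-data
    generator produces sequence sets with controlled GC composition and
    implanted motifs, toy genomes, and expression fixtures for benchmarking
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
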