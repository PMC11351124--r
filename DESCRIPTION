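Package: sorfcp
Title: Coding-Potential Classification of Small Open Reading Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ab initio classification of small open reading frames (sORFs,
    fewer than 100 amino acids) as coding or non-coding from sequence alone.
    Encodes the translation-initiation-site (Kozak) context around the start
    codon as a 36-bit one-hot vector and the in-frame codon (3-mer)
    composition of a fixed-length ORF window (54, 99 or 180 nt) as a
    64-element frequency vector, concatenated into a 100-dimension
    coding-potential representation. Provides dataset construction from a
    genome plus gene annotation (intergenic pseudo-ORF negatives with
    promoter masking and size-class partitioning), a synthetic mini-genome
    generator with a tunable coding signal, exhaustive grid-searched training
    of SVM, k-nearest-neighbour and random-forest classifiers with Platt
    sigmoid probability calibration, a window-routing predictor, and an
    evaluation and reporting layer (confusion metrics, ROC curves,
    balanced/unbalanced harnesses, per-annotation-class positivity and
    multi-metric overlap reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    FNN,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
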