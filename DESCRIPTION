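Package: dimismatch
Title: Discriminative Transcription Factor Binding Models with a
    Di-Mismatch String Kernel
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Learns transcription factor DNA-binding preferences from
    high-resolution in vitro and in vivo data. Protein binding microarray
    (PBM) probe intensities are modeled by support vector regression and
    ChIP-seq peak windows by support vector classification, both in the
    explicit feature space of a di-mismatch string kernel that counts
    matching overlapping dinucleotides between k-mers and zeroes pairs
    below a match threshold. Trained models scan genomic regions in linear
    time through a precomputed k-mer contribution table. The package also
    provides 8-mer E-score, Z-max and PSSM log-odds baseline scorers, a
    feature-analysis procedure that clusters model k-mers to expose
    primary, secondary and cofactor motifs, and seeded synthetic PBM and
    ChIP data generators with planted motif structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    rtracklayer,
    e1071,
    pROC,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
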