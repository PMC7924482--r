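Package: gssnet
Title: Genome-Wide Gene-Start-Site Annotation with Imbalance-Aware
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains a small convolutional neural network to recognise
    299-bp DNA windows centred on gene start sites (GSS), using "limited
    unbalanced" training sets in which Q negative windows are sampled per
    positive window and the positive class is up-weighted by CW = Q in the
    binary cross-entropy loss.  Trained models are applied along whole
    chromosomes with a 1-bp sliding window to produce per-base prediction
    tracks, which are evaluated genome-wide with a metagene signal-to-noise
    statistic (lambda): the mean, over a central window around annotated
    GSS, of the GSS-averaged Z-scored prediction signal.  Includes a
    UCSC refGene/BED annotation reader, a seeded synthetic-genome
    generator with planted promoter-like motifs and CpG enrichment for
    desk-scale benchmarking, CpG-content baselines and promoter-class
    stratification, binned precision-recall, and cross-species scoring
    (train on one genome, scan another).  The network is implemented
    natively (im2col + BLAS convolutions, backpropagation, Adam) so no
    external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr,
    optparse,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
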