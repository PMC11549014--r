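Package: hapformer
Title: Generative Transformer-Based Haplotype Prediction for Small Variant Calling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls small germline variants (SNVs and indels) from aligned
    short reads with a generative sequence-to-sequence model. A transformer
    encoder reads a fixed-width window of the read pileup and two parallel
    transformer decoders emit the sample's two haplotypes as 4-mer tokens.
    Variants are recovered by Smith-Waterman alignment of the generated
    haplotypes to the reference, merged across overlapping windows by
    majority vote, and assigned calibrated phred-scaled qualities by a
    random-forest classifier. Includes a permutation-invariant training
    loss for unordered haplotype pairs, read-backed phase resolution,
    a diploid read simulator for end-to-end testing, and evaluation
    utilities for genotype and phasing accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    ranger,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
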