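#' @import methods
#' @importFrom GenomicRanges GRanges start end width seqnames
#' @importFrom IRanges IRanges
NULL

#' Model architecture configuration
#'
#' Hyperparameters of the encoder/double-decoder haplotype model. Use
#' [hapModelConfig()] to construct one of the named presets. The encoder
#' consumes the `[g, r, 10]` pileup tensor of a window (`g` genomic positions,
#' `r` read rows); each decoder emits up to `maxTokens` 4-mer tokens
#' (148 bases).
#'
#' @slot name preset name.
#' @slot encoderLayers,encoderHeads,embeddingDim transformer encoder geometry.
#' @slot decoderLayers,decoderHeads,decoderDim geometry of each of the two
#'   haplotype decoders (the decoders never share parameters).
#' @slot baseEmbedDim per-base embedding width `d` applied to each pileup cell
#'   before flattening along the read axis (input token size is `d * r`).
#' @slot maxReads read rows `r` per window (row 0 holds the reference).
#' @slot windowSize window width `g` in bp.
#' @slot kmerSize,vocabSize output token k-mer size (4) and vocabulary (256).
#' @slot maxTokens autoregressive decoding cap (37 tokens = 148 bases).
#' @slot ffMult feed-forward width multiplier.
#' @slot dropout dropout probability used during training.
#' @export
setClass("HapModelConfig", representation(
  name = "character",
  encoderLayers = "integer", encoderHeads = "integer",
  embeddingDim = "integer",
  decoderLayers = "integer", decoderHeads = "integer", decoderDim = "integer",
  baseEmbedDim = "integer", maxReads = "integer", windowSize = "integer",
  kmerSize = "integer", vocabSize = "integer", maxTokens = "integer",
  ffMult = "integer", dropout = "numeric"
))

setValidity("HapModelConfig", function(object) {
  msg <- character(0)
  if (object@vocabSize != 4L^object@kmerSize)
    msg <- c(msg, "vocabSize must equal 4^kmerSize")
  if (object@embeddingDim %% object@encoderHeads != 0L)
    msg <- c(msg, "embeddingDim must be divisible by encoderHeads")
  if (object@decoderDim %% object@decoderHeads != 0L)
    msg <- c(msg, "decoderDim must be divisible by decoderHeads")
  if (object@baseEmbedDim %% 2L != 0L)
    msg <- c(msg, "baseEmbedDim must be even (2D positional encoding)")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Haplotype prediction model
#'
#' A transformer encoder plus two parallel, parameter-independent transformer
#' decoders. Construct with [hapModel()]; run with [greedyDecode()] or train
#' with [trainModel()].
#'
#' @slot config a [HapModelConfig-class].
#' @slot params nested list of weight matrices and bias/layer-norm vectors.
#' @export
setClass("HapModel", representation(config = "HapModelConfig", params = "list"))

#' Encoded pileup window
#'
#' The model input for one genomic window: a numeric array of shape
#' `[g, r, 10]` holding ten features per (position, read) cell — one-hot base
#' (4), base quality / 100, consumes-reference flag, consumes-read flag,
#' reverse-strand flag, clipped-read flag, mapping quality / 100. Row 1 of the
#' read axis is the reference sequence (quality feature 1.0, all flags 0).
#' Cells with no aligned base are all zero.
#'
#' @slot window a length-1 `GRanges` giving the genomic window.
#' @slot array numeric array `[g, r, 10]`.
#' @slot readIds names of the reads encoded in rows 2..(k+1) of the read axis.
#' @export
setClass("EncodedRegion", representation(
  window = "GRanges", array = "array", readIds = "character"
))

setValidity("EncodedRegion", function(object) {
  d <- dim(object@array)
  msg <- character(0)
  if (length(d) != 3L || d[3L] != 10L)
    msg <- c(msg, "array must have shape [g, r, 10]")
  if (length(object@window) != 1L)
    msg <- c(msg, "window must be a single range")
  else if (d[1L] != GenomicRanges::width(object@window))
    msg <- c(msg, "array position axis must match window width")
  if (length(msg)) msg else TRUE
})

#' Generated haplotype pair for one window
#'
#' @slot window the decoded genomic window (`GRanges`, length 1).
#' @slot hap0,hap1 generated haplotype base sequences (at most 148 bp,
#'   length divisible by 4).
#' @slot tokens0,tokens1 the underlying 4-mer token ids.
#' @slot tokenProbs0,tokenProbs1 per-token greedy probabilities.
#' @export
setClass("HaplotypePrediction", representation(
  window = "GRanges",
  hap0 = "character", hap1 = "character",
  tokens0 = "integer", tokens1 = "integer",
  tokenProbs0 = "numeric", tokenProbs1 = "numeric"
))

setValidity("HaplotypePrediction", function(object) {
  msg <- character(0)
  if (nchar(object@hap0) %% 4L != 0L || nchar(object@hap1) %% 4L != 0L)
    msg <- c(msg, "haplotype lengths must be divisible by 4")
  if (any(c(object@tokenProbs0, object@tokenProbs1) <= 0) ||
      any(c(object@tokenProbs0, object@tokenProbs1) > 1))
    msg <- c(msg, "token probabilities must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Random-forest variant quality model
#'
#' Post hoc classifier that discriminates true from false variant calls and
#' supplies the phred-scaled QUAL of emitted records (100 trees, maximum
#' depth 25). The feature schema is frozen at fitting time and verified at
#' scoring time.
#'
#' @slot forest fitted `ranger` probability forest.
#' @slot schema ordered feature column names.
#' @slot meta list with fitting metadata (counts, seed, version).
#' @export
setClass("CalibrationModel", representation(
  forest = "ANY", schema = "character", meta = "list"
))

#' Simulated diploid sample
#'
#' Desk-scale test fixture: a random reference, two haplotypes derived from it
#' by planted phased variants, and error-bearing reads aligned back to the
#' reference. File outputs (FASTA/VCF/BAM) are written on demand by
#' [writeSample()].
#'
#' @slot reference named character vector of contig sequences.
#' @slot truth data.frame of planted variants (chrom, pos, ref, alt, gt).
#' @slot reads data.frame of aligned reads (qname, chrom, pos, cigar, seq,
#'   qual, strand, mapq, hap).
#' @slot haps list per contig: the two haplotype sequences and their
#'   coordinate maps back to the reference.
#' @slot config the [simConfig()] list used.
#' @export
setClass("SimulatedSample", representation(
  reference = "character", truth = "data.frame", reads = "data.frame",
  haps = "list", config = "list"
))

setMethod("show", "HapModelConfig", function(object) {
  cat(sprintf("HapModelConfig '%s': enc %d x %dh dim %d | dec 2 x (%d x %dh dim %d) | d=%d r=%d g=%d\n",
              object@name, object@encoderLayers, object@encoderHeads,
              object@embeddingDim, object@decoderLayers, object@decoderHeads,
              object@decoderDim, object@baseEmbedDim, object@maxReads,
              object@windowSize))
})

setMethod("show", "HapModel", function(object) {
  cat(sprintf("HapModel (%s preset), %s trainable parameters\n",
              object@config@name,
              format(paramCount(object), big.mark = ",")))
})

setMethod("show", "EncodedRegion", function(object) {
  d <- dim(object@array)
  cat(sprintf("EncodedRegion %s:%d-%d [%d x %d x %d], %d reads encoded\n",
              as.character(seqnames(object@window)),
              start(object@window), end(object@window),
              d[1L], d[2L], d[3L], length(object@readIds)))
})

setMethod("show", "HaplotypePrediction", function(object) {
  cat(sprintf("HaplotypePrediction %s:%d (%d bp / %d bp)\n",
              as.character(seqnames(object@window)), start(object@window),
              nchar(object@hap0), nchar(object@hap1)))
})

setMethod("show", "SimulatedSample", function(object) {
  cat(sprintf("SimulatedSample: %d contig(s), %d truth variants, %d reads\n",
              length(object@reference), nrow(object@truth),
              nrow(object@reads)))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: %d trees, %d features (%s ...)\n",
              object@meta$num_trees, length(object@schema),
              paste(utils::head(object@schema, 3L), collapse = ", ")))
})

## ---- accessors -------------------------------------------------------------

#' @describeIn EncodedRegion the `[g, r, 10]` feature array.
#' @param x an `EncodedRegion`.
#' @export
regionArray <- function(x) x@array

#' @describeIn EncodedRegion the window as a `GRanges`.
#' @export
regionWindow <- function(x) x@window

#' @describeIn EncodedRegion names of encoded reads (row order).
#' @export
readIds <- function(x) x@readIds

#' @describeIn HapModel the model's configuration object.
#' @param model a `HapModel`.
#' @export
modelConfig <- function(model) model@config
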