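---
title: "Generative haplotype prediction for small variant calling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative haplotype prediction for small variant calling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hapformer)
```

# The model

hapformer calls small germline variants by *generating* the two haplotypes of
a diploid sample directly from aligned short reads, instead of enumerating
candidate alleles and scoring them. The generative model is a transformer
encoder coupled to two parallel transformer decoders, one per haplotype.

**Input encoding.** A 150 bp genomic window is encoded as a numeric array of
shape $[g, r, 10]$ with $g = 150$ positions and $r$ read rows (row 1 is the
reference sequence). Each (position, read) cell carries ten features: the
one-hot base call (4), base quality / 100, a consumes-reference flag (0 for
inserted bases), a consumes-read flag (0 for deletions), the reverse-strand
flag, a clipped-read flag, and mapping quality / 100. The reference row uses
base quality 100 (feature value 1.0) and no flags. Cells with no aligned base
are all zero, and windows with more than $r - 1$ reads are uniformly
downsampled (seeded per window). Reads are sorted by the reference coordinate
of their first aligned base. When a read has an insertion immediately after a
column, that column encodes the first inserted base with the
consumes-reference flag cleared; the generative decoder reconstructs the full
insertion from context. This is one consistent reading of a fixed
one-slot-per-(position, read) layout; the encoding deliberately has no gap
tokens or other special indel machinery.

**Architecture.** Every cell is embedded in $d = 12$ dimensions by a shared
linear layer; a 2D sinusoidal positional encoding (half the channels indexed
by genomic position, half by read row) is added, and all-zero cells are kept
at exactly zero. The $r$ embedded cells of a position are flattened into one
input token of size $d \cdot r$ and projected to the encoder embedding
dimension. The encoder output is projected to the decoder model dimension
$4^4 = 256$ (64 in the CPU `tiny` preset), a standard 1D positional encoding
is added, and the result is the cross-attention memory for two
non-parameter-sharing decoders. Each decoder emits 4-mer tokens (vocabulary
256, big-endian base order A,C,G,T) autoregressively, up to 37 tokens =
148 bases per window. Greedy decoding takes the argmax token at each step,
ties resolved toward the lowest token id.

Named presets reproduce the published size ladder (30M: 6 encoder layers,
8 heads, embedding 800, 4 decoder layers; 50M: 8/8/960/8; 100M:
10/8/1280/10). Two details are resolved here: the feed-forward width equals
the model dimension (a 4x width would inflate the "30M" preset to ~54M
parameters; with equal width the three presets instantiate at 30.3M, 57.1M
and 114.5M), and the 100M preset uses 8 decoder heads because a 256-dim
decoder cannot be split into 10 equal head slices.

# Training

**Targets.** Training windows are labeled (`snv`, `deletion`, `insertion`,
`multi_indel`, `low_complexity_or_poor_mappability`, `true_negative`, with
that precedence) and two 148 bp target sequences are built per window by
applying each haplotype's alleles to the reference; deletions are re-extended
with downstream reference sequence and insertions trimmed, so targets are
always exactly 37 tokens with no pad symbol. Unphased heterozygous variants
are phased by read support: all $2^n$ assignments (up to 4 unphased sites,
all within 100 bp) are enumerated, every read is Smith-Waterman-aligned to
both candidate haplotypes, and the assignment with the highest summed
best-alignment score wins; the returned pair is canonicalized with the
fewer-variant haplotype first, so a lone heterozygous variant sits on
haplotype 1. Regions with unresolvable phase are discarded.

**Loss.** Haplotypes are an unordered pair, so the loss is computed for both
prediction-to-target pairings and only the cheaper configuration
backpropagates (`permutationMinLoss()`); the loss is invariant to target
order by construction. Optimization is AdamW (betas 0.9/0.99) under a linear
warm-up plus cosine decay schedule (defaults 5e-5 to 1e-5; the fine-tuning
variant runs 1e-5 to 1e-6), with global gradient-norm clipping at 1.0. With
`trainModel(keepBest = TRUE)` the returned model is the checkpoint with the
lowest validation loss rather than the last step — the same selection rule
used for the published evaluation model — and the desk-scale study withholds
a slice of its region suite for exactly this purpose.

**Making a 460k-parameter model train on one CPU.** The full-scale method
trains for hundreds of GPU hours on tens of millions of regions; the `tiny`
preset must instead converge within minutes on a few thousand simulated
regions. The architecture above is unchanged, but several initialization and
optimization choices matter enormously at this scale, and all of them are
package design decisions:

* *Pre-norm blocks with final layer norms.* Norm placement is an open choice;
  post-norm did not train at this depth/width without long warm-up.
* *Fan-in initialization and embedding scaling.* Weights use sd
  $1/\sqrt{\text{fan-in}}$ and the token/cell embeddings are initialized at a
  scale comparable to the unit-amplitude sinusoidal encodings; tiny
  (GPT-style sd 0.02) embeddings drown in the positional signal at dim 64.
* *Base-coordinate decoder positions.* The decoder is told where generation
  starts by encoding its positions on the same base-coordinate grid as the
  memory: token $t$ carries the sinusoidal encoding of window offset
  $4(t-1)$. Query and key sinusoids then share one frequency grid, and any
  relative offset is an exact rotation of that basis.
* *A constructive cross-attention alignment prior.* Output token $t$ is
  generated from window columns $4(t-1)+1 \dots 4t$, and sinusoidal
  encodings make this alignment constructible in closed form: head $h$'s
  query projection is initialized to the positional-basis rotation by offset
  $(h-1) \bmod 4$ and its key projection to the identity on a high-frequency
  "ruler" subset of encoding dimensions routed into every head (only the
  high-frequency sinusoid pairs resolve single positions across 150 bp).
  Initial cross-attention is therefore sharply diagonal with one head per
  base offset, and training only has to learn the content mapping. The
  memory projection, token embeddings and cross-attention outputs leave the
  ruler dimensions content-free at initialization so the position signals
  stay clean. With `trainModel(freezeAlign = TRUE)` (the default) the
  query/key projections stay fixed at this prior: the alignment geometry of
  the decoding problem is known exactly, and at desk-scale step counts
  optimizer noise otherwise erodes it faster than the content pathway forms.
* *Zero-initialized residual branches — except the cross-attention output.*
  Self-attention and feed-forward output projections start at zero so the
  network begins as an identity-with-clean-signals map. The cross-attention
  output must NOT start at zero: that would sever the gradient path into the
  values, the memory projection and the entire encoder.
* *Consensus pooling in the flatten projection.* The first $d$ output
  dimensions of the read-flattening projection are initialized to average
  the cell embeddings across read rows, so a column's base consensus is
  extracted identically regardless of which reads happen to cover it
  (coverage composition varies along a window; a random projection
  represents the same base differently under every coverage pattern, which
  stalls early learning).

The compiled kernel in `src/model_kernel.cpp` implements the identical
forward/backward pass as the plain-R reference implementation (`R/nn.R`);
unit tests assert bit-level agreement of losses and gradients between the two
paths, and the analytic gradients are verified against finite differences.

# Variant calling

Calling follows six steps. (1) Candidate regions: every position where at
least 3 reads differ from the reference (mismatch or indel) is flagged,
flanked by 4 bp, and regions closer than 100 bp are merged. (2) Windows of
150 bp start 100 bp upstream of the first flagged position and advance by
25 bp until past the last one. (3) Each window is greedy-decoded and both
haplotypes are aligned back to the reference slice (window plus or minus 30 bp) by a
query-global/subject-local affine Smith-Waterman (match +2, mismatch -4, gap
open -6, extend -1; query-global so terminal indels are never silently
clipped); mismatches become SNVs and gaps become anchored, left-normalized
indels, each carrying the probability of the generating 4-mer token.
(4) Calls are merged across windows by majority genotype vote (a variant on
one decoded haplotype is heterozygous, on both homozygous; ties break toward
heterozygous, the conservative allele count). Minority-window variants are
retained — the quality classifier, not a hard filter, is responsible for
precision. (5) Features are recorded per merged call: windows containing the
call, genotype vote counts and their entropy, cis/trans counts against the
other variants of the region (from co-occurrence on the same or opposite
decoded haplotype in shared windows), min/mean token probability, mean
distance of the call from the window center, pileup depth and alt support,
variant type and length delta. Heterozygous calls connected by consistent
haplotype co-occurrence form phase sets (graph 2-coloring; conflicting
components are emitted unphased) reported through the `PS` tag with phased
`GT`. (6) A random forest (100 trees, depth 25, balanced class weights)
trained on calls labeled true/false against a truth set supplies
$Q = -10\log_{10}(1-p)$, capped at 100, so filtering at Q10 keeps calls with
$p \ge 0.9$ (the default emission threshold).

# The read simulator

`simulateSample()` generates the study conditions end to end: a random
reference (GC 0.42), planted variants at human-like rates (SNVs 1e-3/bp,
insertions and deletions 1.25e-4/bp each, geometric lengths with mean 2,
two-thirds heterozygous with random phase), two haplotypes, and 150 bp reads
drawn uniformly from each haplotype at half depth (default total 50x) with
0.1% substitution errors, rare single-base indel errors, and phred qualities
around 35. Alignments (POS/CIGAR) are derived exactly from the known
haplotype-to-reference edit script before errors are injected, so they are
internally consistent by construction. What the simulator does *not* model —
PCR duplicates, mappability artifacts, insert-size structure,
platform-specific error profiles, clustered errors — bounds what passing
tests can say about real data: they validate the machinery (encoding,
training, decoding, extraction, merging, calibration, evaluation), not
real-genome accuracy.

`makeRegionSuite()` converts a simulated sample into labeled training
examples. Variant windows are placed exactly as the caller places them
(stepping 25 bp from 100 bp upstream of each variant cluster), and each
downsampling replicate jitters the window start within the 25 bp step, so
repeated loci never share a tokenization frame. This mirrors, at small
scale, the published corpus in which every offset of a locus appears as its
own region — and it removes the shortcut of memorizing fixed token
sequences, which a small decoder otherwise discovers faster than copying.

# The desk-scale study

`deskScaleStudy()` is the package's end-to-end experiment: simulate
independent training (8 x 20 kb), calibration (60 kb) and evaluation (80 kb)
samples at 50x / 0.1% error; build ~3000 regions; train the `tiny` preset
(4 epochs, batch 16, warm-up 50 then cosine 8e-3 to 8e-4 — the published
5e-5 schedule belongs to the 30M-100M presets), returning the
lowest-validation-loss checkpoint; calibrate the forest on raw calls from a
calibration sample larger than the evaluation one (100 kb vs 80 kb,
mirroring the published proportions); call the held-out sample; and sweep
the quality threshold over Q0/10/20/30. On these conditions the trained tiny
model reconstructs homozygous SNVs essentially perfectly at the window level,
and the pipeline's hom-SNV sensitivity and precision at Q10 are the study's
headline numbers (`scripts/acceptance.R` recomputes them from scratch).
Heterozygous and indel accuracy at this scale is markedly lower than the
published full-scale figures — separating two haplotypes through two
independent decoders is exactly the part that consumes most of the published
training budget — so those numbers are reported by the training log for
inspection rather than asserted against full-scale benchmarks.

Problem sizes throughout (window 150 bp, r = 32 for the tiny preset, ~3000
training regions, 20 kb contigs) are the package's chosen desk-scale study
conditions.

# Numerical and procedural choices

* Coordinates are 1-based inclusive internally (the Bioconductor
  convention); VCF output is 1-based as required.
* Indel normalization: shared-tail then shared-head trimming, then leftward
  shifting through repeats, re-trimmed; re-normalizing is a fixed point.
* Argmax ties in greedy decoding go to the lowest token id; majority-vote
  ties merge to heterozygous; phase-resolution score ties break by
  lexicographic haplotype order.
* `N` bases encode as an all-zero one-hot with flags set; soft-clipped bases
  are excluded from columns but set the read's clipped flag; mapq-0 reads
  are retained.
* Windows extending past a contig end are clipped and zero-padded with a
  warning; decoding length caps at 37 tokens or the spanned region,
  whichever is reached first.
* The genotype of an allele-correct call with the wrong genotype counts as a
  false positive for classifier calibration (strictest reading); the
  evaluation module tallies genotype mismatches separately.
* Phase-precision bins (1-24, 25-49, 50-100, >100 bp) use the difference of
  VCF POS values; relative phase (cis/trans of adjacent heterozygous pairs)
  is compared rather than absolute haplotype identity.

# Known limitations

* Desk-scale training does not reach the published het/indel accuracy; the
  acceptance-grade quantity at this scale is hom-SNV recovery.
* The evaluation matcher is an exact normalized matcher, not a full
  haplotype-aware comparator: complex representations that only match after
  re-composition count as mismatches.
* The simulator's error model is iid; calibration learned on it will not
  transfer to platform-specific artifacts.
* `low_complexity_or_poor_mappability` labeling accepts any BED; no
  stratification files ship with the package, and stratification-weighted
  fine-tuning is a configuration hook only.
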