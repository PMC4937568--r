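---
title: "accessnet: modelling the sequence basis of chromatin accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{accessnet: modelling the sequence basis of chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

DNase-seq and similar assays mark the genomic sites that are open
(nucleosome-depleted) in a given cell type. Openness is driven largely by
sequence: proteins recognize short degenerate motifs and, in combination,
determine whether a site is accessible in a particular cellular context.
`accessnet` learns that mapping directly. Given a compendium of peak
calls across many cell types, it harmonizes them into one fixed-width
site set with a binary site-by-cell activity matrix, and trains a
multi-task convolutional neural network that predicts, from the 600-bp
sequence alone, the probability that the site is accessible in each cell
type. The trained model is then a measurement instrument: it can be
interrogated for the motifs it discovered, for the influence of each
motif detector on each cell type, and for the predicted consequence of
any single-base change.

## Data harmonization

Peaks arrive per cell type with heterogeneous widths. Every peak is
extended to a fixed width (default 600 bp) around its integer midpoint.
Overlapping peaks are then merged greedily: the closest adjacent pair
(largest overlap) merges first, the merged peak taking the union of the
parents' active cell sets and a midpoint that is the parents' midpoint
average weighted by how many cells each was active in; merging repeats
until no adjacent pair overlaps by more than a bound (default 200 bp).

Decisions the procedure leaves open, and the choices made here:

* Coordinates are BED-convention 0-based half-open everywhere, including
  FASTA extraction.
* When two adjacent pairs tie on overlap, the leftmost pair merges
  first, which makes the greedy order deterministic.
* Merging iterates to convergence (a merged peak may merge again). A
  single left-to-right pass could leave adjacent peaks overlapping by
  more than the bound; iterating is the only reading that guarantees the
  stated postcondition. Weighted midpoints round as `floor(x + 0.5)` so
  results do not depend on banker's rounding.
* Peaks whose extension would cross the chromosome start are dropped by
  default (`edge_policy = "clip"` clips them instead).
* Un-merged peaks weigh as the number of cell types they are active in;
  weights add on merge.

Sequences are one-hot coded as 4 x L indicator matrices (rows A, C, G,
T). `N` encodes as 0.25 in all four rows, so every column sums to one
and an unknown base expresses no preference. Train / validation / test
splits are uniform at random under a recorded seed; the default
fractions (3.5% test, 3.4% validation) mirror the proportions used for
compendium-scale data, and small fractions are appropriate here because
evaluation is multi-task. Encoded datasets and model checkpoints are
persisted as single-file native R (RDS) containers holding named arrays
(sequences, targets, split indices, cell labels; architecture,
parameters, training history).

## The network

One-hot sequence enters a stack of convolution blocks; each block is a
valid (unpadded) cross-correlation of learned filters, batch
normalization with per-filter spatially-shared statistics, a ReLU, and
non-overlapping max pooling. The first layer's filters play the role of
position weight matrices; deeper layers see the spatial arrangement of
first-layer matches. After flattening, fully connected blocks (linear,
batch norm, ReLU, dropout) feed a final linear map to one logit per cell
type; a sigmoid turns these into per-cell accessibility probabilities.
Training minimizes binary cross entropy summed over cells and averaged
over the minibatch, by RMSprop with per-epoch reshuffling and early
stopping on validation loss.

Choices the architecture description leaves open:

* Batch normalization sits between the linear operation and the ReLU;
  running moments use an exponential moving average (momentum 0.9,
  epsilon 1e-5) and are what eval-mode forward passes use, so evaluation
  is deterministic.
* Trailing partial pooling windows are kept (max over the remainder)
  rather than dropped, so no sequence positions are silently discarded.
* Weights initialize from a centered normal scaled by fan-in
  (`sd = 1/sqrt(fan_in)`), biases at zero, under a seed.
* The model is single-strand; no reverse-complement weight sharing or
  averaging (a probe of the synthetic grammar shows filters simply learn
  both orientations when both occur).
* "Unimproved" validation loss means not strictly lower than the best so
  far; the parameters returned are those of the best-validation epoch,
  not the last.
* The default full-scale architecture is conv 300x19 (pool 3), 200x11
  (pool 4), 200x7 (pool 4), fc 1000 + 1000, dropout 0.3 — appropriate
  for millions of training sites. All experiments in this package's
  tests use a reduced architecture matched to the synthetic compendium
  (see below).

The forward and backward passes are implemented in this package on top
of BLAS matrix products: convolution is an im2col gather followed by one
matrix product per layer and batch; the gather, pooling and fused
batch-norm/ReLU inner loops are compiled C++. Gradients — including the
exact backward pass through train-mode batch-norm statistics — are
verified against central finite differences at 1e-4 relative tolerance
in the test suite.

## Transfer seeding

A model trained on a large multi-cell compendium carries most of what a
new, singly-assayed cell type needs. `transfer_seed()` copies every
layer below the output verbatim and re-initializes only the final linear
layer for the new target(s); `finetune_single_pass()` then performs
exactly one epoch of RMSprop updates at half the configured learning
rate. One pass is deliberate: small single-target tasks overfit on
further passes, and the tests confirm a single pass already matches a
fully trained single-task model to within a few AUC points.

## Interpretation

*Filter PWMs.* A first-layer filter is distilled into a position weight
matrix by scanning it over held-out sequences, collecting every
filter-width subsequence whose raw convolution activation exceeds half
the filter's maximum over the whole set, and counting nucleotides per
position. Each supporting subsequence counts once (unweighted); a total
pseudocount of 1 per position (0.25 per base) keeps PWMs defined under
few supports. Filters that never activate above zero are reported dead.
Information content is computed in bits against a background
composition, with the background term added once per position and
`0 log 0 = 0`; for a uniform background the maximum is 2 bits per
position. PWMs export in MEME minimal format so motif comparison against
databases such as CIS-BP can be delegated to standard tools (e.g.
`tomtom -thresh 0.1 -dist pearson filters.meme cisbp.meme`); motif
alignment statistics are deliberately not re-implemented here.

*Influence.* Nullifying a filter replaces its entire post-ReLU
activation map by a single scalar — its mean activation over all
positions of all evaluation sequences — and re-runs the forward pass.
The scalar (rather than per-position) constant is the only reading that
blocks positional information entirely. A filter's influence is the sum
of squares of the per-cell changes in mean prediction; the per-cell
vectors also support clustering filters by which cell types they act on
(Euclidean distance, average linkage).

*Motif insertion.* The complementary, motif-centric probe inserts a
given motif (consensus or PWM samples) into the center of a set of
sequences and reports the per-sequence, per-cell prediction change.

## Variant scoring

*Saturation mutagenesis* evaluates all 3L single-base mutants of an
L-bp sequence in batched eval-mode forward passes. Each position gets a
loss score (reference prediction minus the minimum over the three
mutants) and a gain score (maximum over mutants minus reference);
`gain + loss >= 0` always. The heat-map plot draws reference-base
letters scaled by loss score beyond a minimum height (default 5% of the
maximum).

*SAD profiles.* A variant's SNP Accessibility Difference profile is the
per-cell difference in predicted accessibility between its alternative
and reference alleles, computed on the genome window centered on the
variant (the variant sits at 0-based offset `floor(L/2)`; the window
choice is this package's, as no convention is forced by the score's
definition). VCF input is 1-based and converted at the boundary; only
SNVs are scored, indels are skipped with a logged reason, multi-allelic
records yield one profile per alternative allele, and a reference-allele
mismatch against the genome is an error naming the position.
`rank_variants()` orders profiles by the largest absolute per-cell SAD
and flags those whose absolute profile mean exceeds 0.1 — a ten-point
average change in predicted accessibility.

## The synthetic compendium

Every quantitative claim in the tests is made against a simulator with
known ground truth, because only there are the causal features of every
site and variant known exactly. The generator emulates a multi-cell
peak compendium at desk scale:

* Background sequence is i.i.d. with a mildly AT-rich composition
  (A = T = 0.30, C = G = 0.20), echoing mammalian genomic background.
* Three motifs echo well-known accessibility-associated factors: an
  AP-1-like 7-mer (`TGASTCA`), a CTCF-like 19-mer, and a GC-box-like
  8-mer. PWM cores are sharp (dominant base probability 0.98; designated
  degenerate positions split evenly), mimicking real TF motifs whose
  cores are nearly deterministic.
* Motif presence is made a deterministic property of the sequence, which
  is what "learnable by construction" requires. Two measures achieve
  this. Planted instances are drawn from the PWM *conditioned on
  scoring above half of the PWM's maximum score* — functional,
  high-affinity sites, the same half-max threshold used for filter
  interpretation. And the background is rejection-cleaned: any window
  scoring above that threshold for any grammar motif, on either strand,
  is redrawn until none remains. Without cleaning, a short A/T-rich
  7-mer arises by chance in a fair fraction of 600-bp AT-rich windows,
  which would decouple labels (defined by plants) from sequence and put
  a hard ceiling on attainable accuracy for its cognate cells. With
  both measures, a classifier with access to the true plant locations
  achieves AUC 1.0 at zero label noise, and a sequence-based learner
  can approach it up to the label noise.
* Each motif plants independently with probability 0.35 per site,
  uniformly within the central half of the site, strand uniform (the
  PWM reverse-complemented on minus plants); overlapping plants re-draw
  their position up to ten times and are skipped if no room is found.
* A site is active in a cell exactly when it carries a cognate plant
  (AP-1-like: cells 1–2; CTCF-like: cells 2–3; GC-box: cells 3–4 — the
  overlap gives cells shared and private grammar), after which each
  label flips with probability 0.05. With the default plant probability
  this yields per-cell activity rates of roughly 35–58%, comparable to
  the denser end of real compendia.
* The compendium can be written out as a concatenated synthetic genome
  (FASTA) with spacers, a site BED, per-cell jittered peak BEDs with a
  manifest, an activity table, and a VCF of labeled variants: causal
  SNPs substitute the most informative position of a planted instance
  with the motif's least probable base (destroying the match by
  construction), bystander SNPs hit background at least 10 bp from any
  plant.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: cooperative or distance-dependent motif
grammar, dinucleotide background structure and repeats, shape/flanking
effects, chromatin state unexplained by local sequence, and measurement
artifacts of peak calling. Results on the grammar bound what the code
can do, not what any particular genome will yield.

## Problem sizes and settings used by the tests

The packaged experiments run on one CPU, so the study conditions are
desk scale by design: the learnability experiment uses the default
grammar (10,000 sites x 4 cells x 600 bp, label noise 0.05) with a
reduced architecture of two convolution blocks (50 filters of width 19,
pool 15; 50 of width 5, pool 4) and one fully connected layer of 60
units, dropout 0.3. Training uses minibatches of 64, RMSprop at
learning rate 0.01 with decay 0.9, L2 weight decay 1e-3 on weight
matrices, and up to 10 epochs. The weight decay matters in this
small-data regime: without it, validation loss degrades from epoch ~5
while weight components that receive no gradient signal retain their
random initialization indefinitely (RMSprop's normalization turns even
vanishing gradients into learning-rate-sized steps, so unconstrained
weights jitter rather than decay). The coarse first pooling (15
positions) reflects that site labels do not depend on motif position.
Transfer seeding is demonstrated on a 4,000-site, 300-bp variant of the
grammar, holding one cell out of pretraining (minibatch 32 there, so a
single fine-tuning pass contains enough updates to fit the fresh output
layer). Saturation mutagenesis summaries use 50 active sites; variant
discrimination uses 100 causal and 100 bystander SNPs. The first-layer
filter width of 19 matches the widest planted motif so a single filter
could in principle represent it.

## Numerical notes and limitations

* Ranking metrics use midranks for ties (AUC is the Mann-Whitney
  statistic); cells lacking a class in the evaluation split report NA
  and are excluded from means. Precision-recall areas use step-wise
  interpolation over distinct thresholds.
* Batch-norm running moments make eval-mode prediction deterministic;
  all stochastic steps (weight init, shuffling, dropout, simulation)
  derive from explicit seeds, and equal seeds reproduce training
  bit-for-bit.
* Biases of layers followed by batch normalization are redundant (the
  mean subtraction absorbs them exactly); they are kept fixed at zero
  during training. Letting the optimizer touch them would not change
  the learned function, but RMSprop turns their near-zero gradients
  into a random walk that shifts the raw activation scale against which
  filter interpretation thresholds — so they stay at zero. The output
  layer's bias, which no batch norm follows, trains normally.
* At this training scale the network solves the task with *distributed*
  motif representations: several first-layer filters each capture a
  portion of a long motif, and the deeper layers compose them. The
  CTCF-like 19-mer in particular is never consolidated into a single
  filter — partial detectors are sufficient for discrimination (the
  cleaned background contains no partial decoys), so no gradient
  pressure completes them, and once predictions saturate the residual
  gradient is dominated by label-noise examples that cannot be fit.
  The consequence is visible in the half-max filter PWMs: the
  best-matching filter per planted motif carries clearly more influence
  than the median filter and aligns to the plant, but its PWM is softer
  and lower-information than the planted PWM (measured per-position
  total-variation distances of roughly 0.27/0.53/0.42 for the
  AP-1-like/CTCF-like/GC-box plants, and filter information contents of
  about 4-6 bits against plant values of 12-35). Single-filter motif
  recovery at near-plant information content should therefore not be
  expected from models of this size; the corresponding checks in the
  test suite document this as a standing limitation rather than hiding
  it.
* The trainer holds the encoded dataset in memory (4 x L x N doubles;
  about 190 MB for the default synthetic compendium); compendium-scale
  corpora would need chunked storage, which is out of scope here.
* Training time scales linearly in sites x length x filters; the
  default synthetic experiment trains in about six minutes on one CPU.
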