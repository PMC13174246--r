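---
title: "Matched-mask denoising autoencoders for reference-panel genotype imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched-mask denoising autoencoders for reference-panel genotype imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Across-population genomic selection needs the training and prediction
populations to be genotyped at the same marker positions. Breeding
populations, however, are typically genotyped on different low-density
chips, so their marker sets A and B overlap little or not at all. With a
high-density reference panel P (a missing-free set of fully genotyped
individuals), the missing positions can be *imputed*: each population is
reconstructed onto the shared set `(A | B) & P`, after which ordinary
genomic prediction (GBLUP) runs across populations.

Two missingness regimes matter:

* **systematic** — a marker is absent in *every* sample (off-chip for the
  whole population); this is what reconstructive imputation must fill;
* **sporadic** — entries missing at random per sample (assay dropouts);
  this is the general imputation task.

`matchimpute` imputes both with a residual convolutional denoising
autoencoder trained per window of markers, using a reference panel as the
clean training signal.

## Genotype encoding

Biallelic genotypes are coded 1 (A1A1), 2 (A1A2), 3 (A2A2) with 0 for
missing, where A1 is the reference-genome allele. Before entering the
network each code becomes a binary channel triple: `[0,0,0]` for missing,
`[1,0,0]`, `[0,1,0]`, `[0,0,1]` for codes 1–3. The zero triple at missing
positions means corruption and absence share one representation: the
network's input literally lacks the signal it must reconstruct.

## The matched-mask idea

A denoising autoencoder learns to reconstruct clean genotypes from
corrupted input. The training corruption is the design decision that
matters most: random masking teaches the network to fill *random* gaps,
while at prediction time the gaps follow the target's chip layout —
systematic columns plus each sample's own dropouts. The matching
algorithm builds the corrupted training set so that its missingness
patterns are exactly the patterns in the target:

1. encode panel (`Tr`, n samples) and target (`Te`, m samples);
2. mean-fill `Te`'s missing entries with the panel's per-marker mean code;
3. compute the n × m Manhattan distance matrix between panel samples and
   filled target samples;
4. average each target sample's distance to all panel samples;
5. order target samples by *descending* average distance (most atypical
   first, so they are not starved of good matches);
6. each target sample in turn claims its nearest still-unclaimed panel
   sample (without replacement) and stamps its missing positions onto it;
7. passes over the ordered target list repeat until every panel sample is
   claimed.

Every corrupted training row therefore carries the missingness of a real
target sample, and under a systematic pattern all rows carry exactly the
systematic columns.

For general imputation the target's own observed genotypes are also worth
training on. The target is first KNN-imputed (k = 5 by default; Manhattan
distances on mean-filled codes, majority vote among the k nearest
samples), then stacked under the panel as *augmented* training rows. Each
augmented row is corrupted with a missingness pattern borrowed from
another target sample: pairwise distances among the KNN-imputed rows are
computed with the diagonal set to twice the matrix maximum so no sample
matches itself, the samples are arranged in both descending and ascending
order of average distance, and each pass matches every arranged sample to
its nearest remaining row (a fresh without-replacement pool per pass),
unioning the masks of the two passes.

Two wrinkles deserve a note, because the procedure's natural-language
description is ambiguous:

* **Which positions are stamped on an augmented row.** We stamp the
  arranged sample's missing positions onto the matched row, *minus* the
  matched row's own originally-missing positions. At those positions the
  "clean" value is a KNN guess, not an observation — masking them would
  train the network toward a guess. The same positions are excluded from
  the loss for that row. The single coherent reading of the dual-pass
  step is adopted: each pass keeps its own without-replacement pool (a
  shared pool would leave the second pass empty-handed), and a row's
  masks are the union over passes.
* **When masks are regenerated.** Matching is deterministic given the
  data, so regenerating masks each epoch would reproduce the same masks;
  they are computed once per window. A `remask_per_epoch` option exists
  and only changes behaviour for the stochastic random-masking ablation.

Ties anywhere (equal average distances, equal nearest distances, tied KNN
votes) resolve to the smallest sample index or smallest genotype code, so
the whole pipeline is deterministic. When the panel outnumbers the target
(n > m) the ordered target list is cycled; when n < m, matching stops once
panel rows are exhausted.

## The network

Eight 1-D convolutions with input channel counts 3, 32, 64, 64, 128, 64,
64, 32, kernel 15, stride 1, padding 7. ReLU follows each convolution;
layer normalisation (over channels, per position and sample, with
per-channel gain/bias) follows ReLU, or sits before the identity addition
inside a residual block. Max-pooling (factor 2) follows encoder stages 2
and 4; upsampling (repeat ×2) precedes decoder stages 6 and 8 — the
symmetric hourglass implied by the channel sequence. Identity skip
connections wrap the two channel-preserving 64→64 stages (one in the
encoder, one in the decoder): each fits a residual `F(x)` with output
`F(x) + x`, which converges faster than fitting the mapping directly.
The final stage maps 32 channels to 3 genotype score channels; imputed
codes are the per-position argmax, and observed inputs pass through
unchanged.

Window lengths are padded internally to a multiple of 4 (zero channels,
excluded from the loss and cropped on output) so the two pool/upsample
pairs preserve length; windows shorter than 4 markers are rejected.

Training minimises the 3-class cross-entropy between the scores on the
corrupted input and the clean codes at all positions whose clean genotype
is genuinely known — originally-missing truth is excluded. Whether the
loss should cover all known positions or only masked ones is not
determined by the method description; the default is all known positions
(a denoising autoencoder reconstructs the whole signal, and unmasked
positions anchor the identity mapping), with `loss_scope = "masked"`
available. Optimisation is Adam (lr 1e-3, eps 1e-8, weight decay 1e-5),
batch 64, at most 150 epochs. The monitored quantity is the full
training-set loss recomputed after each epoch (there is no validation
split to monitor); parameters are checkpointed whenever it improves and
the checkpointed best model does the predicting. From epoch 101 the
learning rate is multiplied by 0.9 after every epoch without improvement
(patience 0, min mode) — early epochs keep the full rate, late epochs
anneal into the minimum.

Dropout is applied after the two pooled encoder stages and the
bottleneck, at a rate tied to the corruption level of the window's
training input: `0.3 − (mr − 0.1)/8`, where `mr` is the fraction of
missing codes in the corrupted training matrix (computed per window,
since the window is the training unit). Heavier corruption already
regularises, so the rate decreases linearly in `mr`.

A single integer seed controls weight initialisation, batch shuffling and
dropout; identical seeds give bit-identical training histories.

### Ablation switches

`network_config()` exposes the reduced variants as flags: `matching`
(random masks at the target's missing rate instead of matched masks),
`augmentation` (no stacking of KNN rows), `residual`, `layernorm`,
`batchnorm` (batch statistics per channel instead of layer
normalisation), `dynamic_lr`. The acceptance suite checks the headline
direction: disabling matching costs the most accuracy.

## Windows and orchestration

Chromosomes are processed in windows of 1000 markers (configurable).
Forward windows `[0, w), [w, 2w), ...` train and impute themselves; a
terminal remainder of r markers is handled by a *reverse* window that
trains on the last w markers but imputes only the remainder, so terminal
regions see a full-width training context. The impute spans partition the
chromosome; each marker is imputed by exactly one window.

`general_impute()` restricts target and panel to their shared loci (the
panel's private markers are never imputed; unshared target loci are
dropped and counted), corrupts the panel by matching, augments, trains
and fills only the originally missing entries. `reconstructive_impute()`
first forms the output marker set `(A | B) & P`, appends the `B \ A` loci
as all-missing systematic columns (with panel-derived alleles), and runs
the same machinery without augmentation — on the reconstructive task the
augmented rows add little, at real computational cost, so they are
omitted. `two_way_impute()` is two independent one-way runs, giving both
populations the identical `(A | B) & P` marker set.

Allele consistency between target chips and panel is checked by
`(chrom, pos)` key and ref/alt pair; mismatched (including swapped)
alleles are dropped with a warning rather than strand-flipped — silent
flips corrupt codes undetectably, and nothing in the method description
licenses them.

## Accuracy metrics

Genotype concordance rate (CR) is the fraction of originally-missing
genotypes imputed to the true code; a genotype is concordant only when
both alleles match. Allelic CR counts allele-level overlap (an imputed
heterozygote against a homozygous truth gets one of two alleles), so
genotype CR never exceeds it. Genotype r² is the squared Pearson
correlation of the integer codes over masked entries, reported as
undefined — never as zero — when either vector is constant (an
all-heterozygous truth, for example). The MAF breakdown bins loci by
truth-derived minor-allele frequency into (0, 0.05], (0.05, 0.1],
(0.1, 0.2], (0.2, 0.3], (0.3, 0.4], (0.4, 0.5]; frequencies come from the
evaluation truth rather than the panel because that is the quantity the
held-out comparison conditions on. Mask generators produce both study
patterns: systematic (whole columns) and sporadic (per-sample entries),
with `round(rate * p)` masked units (ties to even).

## The synthetic testbed

Real panels and breeding populations cannot ship with a package, so the
testbed generates them. Founder haplotypes (6 by default) carry alleles
at per-locus frequencies bounded away from fixation (`maf_floor` 0.05);
each sample haplotype copies one founder and switches to a random founder
between adjacent markers with probability 0.02, plus rare flips (1e-3) —
a first-order haplotype-copying mosaic. This produces the two features
imputation feeds on: marker–marker LD that decays with distance (adjacent
r² ≈ 0.2 at the defaults, matching the long LD blocks of elite breeding
material with few effective founders) and panel–target relatedness
(populations are drawn from the panel's founders; an `unrelated` switch
provides the negative control). Derived populations receive marker
subsets of configurable overlap, emulating two chip designs down to
completely non-overlapping ones. Phenotypes are additive on −1/0/1
genetic values, with effects at random QTL and residual noise set to a
target heritability.

What the mosaic does *not* emulate: recombination-map heterogeneity,
selection, population structure beyond founder sharing, genotyping error,
and hybrid pedigrees. Green tests on this testbed show the machinery is
correct and directionally faithful — not that real-data accuracy numbers
transfer.

## GBLUP demonstration

The across-population payoff is measured with GBLUP: `y = Xβ + a + e`,
`a ~ N(0, G_a σ_a²)`, with the VanRaden relationship matrix
`G_a = WW' / (2 Σ p_j(1 − p_j))` over centred −1/0/1 marker values of the
stacked training and test sets (which must share one marker set — the
contract the imputation establishes). The variance ratio is estimated by
REML profiled over h² on the eigenbasis of the training-block `G_a`
(simple, exact, stable at desk scale); fixed effects are an intercept.
Predictability is the Pearson correlation of predicted and observed test
phenotypes. At a fixed variance ratio the predictions coincide with the
ridge-regression closed form, which the tests exploit as an independent
oracle.

## Numerical choices and problem sizes

* Convolutions run as im2col + BLAS matrix products (C++); everything is
  double precision.
* He-normal weight initialisation; normalisation epsilon 1e-5.
* Per-window training seeds derive deterministically from the
  configuration seed and the window counter.
* Degenerate inputs: a window with no known genotypes errors; a marker
  missing in every target sample of a general run is seeded with the
  panel's majority code for the KNN fill only (it stays excluded from
  loss and masks); REML falling into a degenerate likelihood falls back
  to h² = 0.5 with a flag.
* The shipped test and acceptance runs use scaled-down problems —
  windows of 60–200 markers, panels of 48–200 samples, 20–50 epochs —
  chosen so the full pipeline (simulation, matching, training, two-way
  imputation, GBLUP) is exercised end to end at desk scale.

## Known limitations

Only biallelic SNPs are modelled; multi-allelic records and indels are
skipped on input. No phasing, no dosage output, no genotype-likelihood
handling. Mismatched alleles are dropped, never flipped. The REML is
intercept-only (no environments or replicates). Imputation quality on
rare alleles follows the usual pattern — minor-allele CR falls as MAF
falls — and the GBLUP consumer is chosen partly because it tolerates
that.
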