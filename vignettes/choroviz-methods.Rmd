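---
title: "Quantifying and classifying the choroidal vascular running pattern"
author: "choroviz"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and classifying the choroidal vascular running pattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(choroviz)
```

## The measurement model

The large vessels of Haller's layer drain toward the vortex veins, and in
a normal right eye the posterior pole splits at a horizontal watershed
through the macula and disc: upper-hemifield vessels run up-left (toward
the upper-temporal vortex vein), lower-hemifield vessels down-left.
`choroviz` treats "is the running pattern symmetric about the watershed?"
as a supervised two-class problem and derives everything from a square
8-bit grayscale en-face slab in which vessels are dark.

All orientation mathematics assumes the right-eye (OD) frame with the
temporal side on the left. Left eyes are mirrored left-right by
`normalize_laterality()` before measurement; the operation is idempotent
and a strict mode can refuse OS input instead. The physical pixel pitch
defaults to 7/512 mm/px (a 7 x 7 mm macular scan at 512 x 512 px) and
scales every mm-valued feature; area features scale with its square,
ratio features are scale-free (a tested invariant).

## Vessel quantification pipeline

**Binarization.** Otsu's discriminant-analysis criterion on the 0..255
histogram; pixels at or below the threshold (dark = vessel) become
foreground. Among tied maximizers of the between-class variance the mean
tied level is used, which centers the cut between well-separated modes.
A constant image is rejected.

**Denoising.** 8-connected components smaller than a cutoff are removed
and enclosed background holes smaller than the same cutoff are filled.
The cutoff defaults to 30 px at 512 x 512 and scales with the squared
image-size ratio; it is exposed in `choro_config()` because the choice
of operator is an implementation decision; the clinical protocol only
asks for a denoised mask.

**Skeletonization.** Two-subiteration parallel Zhang-Suen thinning to a
fixpoint. One deliberate correction: the neighbor-count window is 3..6
instead of the original 2..6. We verified (against two independently
written ports) that the unmodified parallel scheme deletes both borders
of a constant-width 45-degree band in the same subiteration and can
erase such a vessel entirely; requiring three neighbors protects
diagonal strokes while leaving ordinary thinning unchanged. This is the
same family of fix that practical thinning implementations ship. The
residual one-sided staircase steps are removed by `prune_skeleton()`
before graph analysis — a pixel with 2-3 neighbors that remain mutually
8-connected without it is redundant; without this pass, staircase
corners (3 neighbors each) masquerade as bifurcations and shatter
shallow-angle vessels into micro-segments.

**Segment graph.** Bifurcations are skeleton pixels with 3 or more
neighbors; the pruned skeleton minus those pixels decomposes into
maximal paths, each attached back to its terminal bifurcations. A
segment's orientation is the chord angle between its endpoints, in
[0, 180) degrees with y increasing upward — the simplest reading of
"the angle of each line segment"; per-pixel tangents would be noisier at
this caliber. Segments shorter than 5 px (configurable) are excluded
from orientation statistics but their pixels still count toward length
totals.

**Oblique classification.** Upper hemifield: 95-175 degrees natural,
5-85 unnatural; lower hemifield: the reverse. The two 10-degree slack
bands around horizontal and vertical are "neither" and enter neither
numerator nor denominator of the oblique percentages, which follow
directly from the printed band limits. Percentages are length-weighted:
length weighting is stable under resampling and matches "ratio of ...
vessel" better than segment counting. Hemifield membership is decided by
the path midpoint row; segments whose path crosses the midline feed the
two watershed-crossing ratios (fraction of crossers in each diagonal
band) — the crossing definition is our interpretation of a quantity whose
clinical description names it without a formula.

**Ladder pattern.** Horizontal lines every 25 px (first line one strip
inside the border, 1-based rows 25, 50, ...); at each column a 7-px
strip votes, and a strict majority of vessel pixels yields a white
ladder pixel (strips are clipped at the border and the majority is over
the available rows). Maximal white runs along a line are the horizontal
cross-sections of vessels, so within a half-image the run-length sum is
the ladder "total length" and the mean run length the caliber proxy.
Upper/lower and temporal/nasal differences are signed in the OD frame
(upper minus lower, temporal minus nasal); an absolute-value variant
would lose the direction of the caliber imbalance.

**The 28 features.** `feature_names()` fixes the order: region-wise
area/length/caliber (1-8), crossing ratios (9-10), oblique percentages
and their ratios/differences (11-20), and ladder contrasts (21-28). Rows
17 and 18 are read literally as ratio and difference of features 15 and
16. Zero-denominator ratios (an eye with, say, no unnatural vessels) are
mapped to a cap of 100 (configurable), and every quotient is clamped to
that magnitude: degenerate eyes stay finite for the classifiers, at the
cost of making the capped ratio features strongly non-linear near
perfection (see "Limitations"). The (mm) annotations on ratio rows are
treated as dimensionless, since a ratio of two lengths carries no unit.

## Classifiers

**GAFS-SVM.** An RBF-kernel SVM on z-scored features (training-fold
statistics only). No reference values exist for C and gamma, so
the default is an internal stratified 5-fold grid search over
C in {0.1, 1, 10, 100} and gamma in {0.001, 0.01, 0.1, 1} by accuracy.
Feature selection is a binary-mask genetic algorithm with the published
settings — population 20, one-point crossover at 0.7, mutation at 0.2,
tournament size 2, at most 1000 generations with early stopping — and
elitism, so best-so-far fitness is nondecreasing. The mutation rate is
read as a per-individual event (a mutated individual flips each gene
with probability 1/28); the per-gene reading is available via
`gafs_config(per_gene = TRUE)`. Fitness is internal stratified 5-fold CV
accuracy of the wrapped SVM at fixed default hyperparameters (cost 1,
gamma 1/k), cached per mask; accuracy rather than AUC because the
selection's effect is reported downstream in accuracy/kappa terms.
Early-stopping patience (for which no reference value exists)
defaults to 100
improvement-free generations; desk-scale runs in the tests and the
acceptance script use 25 generations with patience 8, which reaches an
internal fitness plateau on the benchmark in a few generations.

**Confidence scores.** CS is the probability of the symmetric class
(CS of 1 = confidently symmetric); classification thresholds CS at 0.5
with asymmetry as the positive class and the tie going to the negative
(symmetric) class. For the SVM, CS comes from Platt scaling implemented
in-package: a regularized sigmoid fitted to the training decision
values. We do not use the backend's built-in probability mode because
its internal cross-validation draws from a C random stream that cannot
be seeded from R (making scores order-dependent between runs) and its
probabilities can disagree with the decision boundary near the margin;
the in-package calibration is deterministic and monotone in the decision
value.

**Embedding pathway and fused forest.** The image pathway is a pluggable
embedding extractor. The default for benchmarks is a pixel embedder
(bilinear resize to 32 x 32, per-image standardization, flatten) whose
information is concentrated by PCA; a compact two-layer convolutional
network trained with SGD (learning rate 1e-4, momentum 0.9, batch 32,
binary cross-entropy, horizontal/vertical flips and 15-degree rotations
as augmentation) is provided as `cnn_embedder()`, standing in for a
large pretrained backbone, whose embedding is the flattened last
convolution layer. Any externally computed embedding can be plugged in
unchanged. Embeddings are reduced to 100 principal components (fitted on
training rows only, truncated at the rank bound with a warning) and
concatenated with the 28 features; the random forest on the 128 fused
columns reports CS as the fraction of trees voting symmetric and
normalized Gini importances. The published forest used 100000 trees —
the package default — while tests and the acceptance benchmark override
to 500, which changes the vote fractions negligibly.

## Evaluation

Folds are stratified (the cohort being near-balanced makes this the
faithful, lower-variance reading of "randomly divided"), shared across
models — a requirement for the paired Wilcoxon comparison to be
meaningful — and deterministic per seed. Metrics use asymmetry as the
positive class; kappa is unweighted Cohen's kappa on the 2x2 table, with
the degenerate all-one-class table scored 1 for perfect agreement and 0
otherwise. Fold summaries report across-fold sample SDs. The Wilcoxon
signed-rank test drops zero differences, mid-ranks ties, and is exact
(full distribution of the positive-rank sum by convolution over
half-rank units) up to 15 informative pairs, beyond which a normal
approximation with continuity and tie correction takes over. Everything
fitted — scaling, feature selection, embedder, PCA, hyperparameters —
is fitted inside each training fold only.

## Confidence vs human agreement

The strength of confidence is |CS - 0.5|, cut into exact thirds of
[0, 0.5]: below 1/6 unconfident, below 1/3 moderately confident,
otherwise confident. The conventional three-decimal bin bounds
(0.166/0.167, 0.332/0.333) leave 0.0005-wide gaps; implementing the
thirds exactly (with half-open intervals and a 1e-9 guard for scores
sitting on a bound) removes them. Agreement groups count how many of
three independent raters match the supervised label (3/2/1/0 ->
agreement / partial agreement / partial disagreement / disagreement).
`simulate_raters()` flips each true label independently per rater, with
optional per-eye difficulty multipliers so that eyes the classifier
finds hard can also be the eyes raters misread — the regime in which the
unconfident fraction concentrates in the disagreement group. The module
is model-agnostic: any classifier's CS can be analyzed, with the fused
forest as the default source.

## The phantom generator

`synth_config()` renders dark anti-aliased capsule strokes (trunks plus
branches) on a brighter background, adds Gaussian pixel noise, and
quantizes to 8 bits. Defaults: 256 px images (512 supported; 256 keeps
the full test suite fast), 5 trunks with 2 branches per hemifield,
caliber 6 +/- 1 px, vessel/background intensities 70/180, noise SD 8 —
a contrast and density regime chosen to look like a plausible Haller
slab while remaining unambiguous to a human eye. The asymmetry knob
alpha in [0, 1] drives three effects: a fraction alpha of
upper-hemifield strokes (0.3 x alpha of lower ones) flips into the
opposite orientation band; half of the flipped strokes are dragged onto
the watershed so vessels visibly cross it; and lower-hemifield calibers
inflate by 1 + alpha. The flip bias toward the upper hemifield mirrors
the described asymmetric phenotype (counter-drainage vessels
concentrated in the upper area) and makes the bounded hemifield
contrasts — e.g. f20, the upper-lower natural-percentage difference —
monotone in alpha in expectation, which the tests check. With symmetric
flipping the ratio-difference feature f18 would sit near zero at every
alpha, so no monotonicity statement about asymmetry would be testable on
it; see "Limitations" for why f18 is ill-behaved regardless. The class
label is symmetric when alpha is below 0.5. The standing benchmark is
200 eyes at alpha 0.1 vs 0.9, seed-driven end to end.

What the phantoms do not emulate: OCT speckle and shadowing, vortex-vein
ampullae, caliber tapering along a vessel, curvature, and the genuinely
ambiguous mid-spectrum eyes that make the clinical problem hard. Passing
the benchmark therefore demonstrates that the pipeline measures what it
claims and that the classifiers learn from those measurements — not that
clinical-grade accuracy is achieved on real eyes.

## Numerical choices and degenerate inputs

* Hemifields are split half-open at row H/2 (upper rows first); the
  temporal half is the left half of the OD frame.
* Orientation is undefined for closed loops and single pixels; such
  segments are "neither" and never enter orientation statistics.
* An empty mask after denoising raises "no vasculature detected"; a
  constant image fails binarization explicitly.
* Segment paths measure length in the (1, sqrt 2) step metric, which
  overestimates straight lines by at most ~8%; region length totals use
  raw skeleton pixel counts, as specified for the area/length/caliber
  features.
* All randomness (phantoms, folds, GA, forests, rater simulation) is
  seed-controlled through function arguments; nothing reads the global
  RNG state without restoring it.

## Known limitations

* The capped ratio features (7, 15-17, 19, 23-24, 27-28) are hyperbolic
  near perfect symmetry: a hemifield with 1% unnatural length maps to a
  ratio of 99 while 0% maps to the cap of 100, so expectations of
  |f18| = |f15 - f16| are dominated by sampling noise near alpha = 0 and
  are not monotone in asymmetry under any flip design. The bounded
  percentage contrasts (f12, f14, f20) carry the same information with
  stable statistics; monotonicity is asserted on f20.
* Overlapping near-parallel vessels merge into a single centerline, so
  skeleton length under-reports total vessel length where trunks cross;
  the 10% length-recovery property is therefore tested on single-trunk
  phantoms.
* Thinning erodes a stroke's rounded caps by roughly half a caliber at
  each end, and 2x2 pixel blobs vanish entirely (inherited from the
  parallel thinning scheme; below the denoising floor in practice).
* The built-in CNN is a compact stand-in: with the stated SGD settings
  its value on strongly separable phantoms comes mostly from the
  convolutional feature geometry rather than long training, which is
  sufficient here (a linear probe on held-out embeddings exceeds 0.8
  accuracy) but is no substitute for a pretrained backbone on clinical
  data.
* Image-quality and refraction exclusion criteria applied at acquisition
  time have no image-derivable definition here; they are metadata
  filters on the manifest, not computations.
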