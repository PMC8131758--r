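---
title: "Methods: deep-learning-assisted scoring of the in vitro micronucleus assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-learning-assisted scoring of the in vitro micronucleus assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and the scoring problem

The in vitro micronucleus (MN) assay quantifies DNA damage by counting small
extra-nuclear DNA bodies (micronuclei) left behind when a chromosome or
fragment fails to join a daughter nucleus after division. In the
cytokinesis-block (Cyt-B) variant, cultures are arrested after one division so
that once-divided cells appear binucleated (BN); the genotoxicity endpoint is
the percentage of BN cells carrying at least one MN, and the ratio of
mono-, bi- and polynucleated cells measures cytostasis. In the unblocked
variant the endpoint is the percentage of micronucleated mononucleated (MONO)
cells and cytotoxicity comes from post-recovery cell counts.

Scoring thousands of single-cell images per culture by hand is slow and
subjective. `mnscore` implements an automated scoring pipeline for
two-channel (brightfield + DNA stain) single-cell images: every object is
classified into one of six classes —

MONO, MONO_MN, BN, BN_MN, POLY (3–4 nuclei), and IRREG —

where IRREG collects irregular morphologies (overlapping nuclei, nuclei of
unequal size or staining intensity, irregular nuclear shapes) that standard
scoring criteria exclude. Per-file class counts then feed the OECD Test
Guideline 487 statistics.

## Synthetic imagery: what it emulates and what it does not

No public single-cell image corpus accompanies this problem, so the package
ships a generator (`render_cell()`, `generate_labeled_dataset()`,
`generate_dose_response_cohort()`) that produces two-channel images with
*known* truth labels. Each cell is a cytoplasm disk (brightfield channel)
containing 1–4 nuclear disks and 0–2 micronucleus disks (DNA channel),
followed by Gaussian blur and additive Gaussian sensor noise. The noiseless
DNA image thresholded at `mask_threshold` gives a mask with exactly
`n_nuclei + n_mn` connected components, which is the invariant the rendering
tests check with an independent flood-fill oracle.

Key parameter choices (all configurable in `synth_config()`):

* **Image scale.** 64×64 px with nucleus radii 8–12 px. This is a desk-scale
  convention chosen so a CNN trains in minutes on one CPU; it does not
  reproduce any instrument's magnification or pixel pitch.
* **MN size.** MN diameter defaults to 1/16–1/3 of the main-nucleus diameter,
  the conventional microscopy criterion for calling an object a micronucleus.
  It is a knob because published criteria are applied with judgment in
  practice.
* **MN placement.** Inside the cytoplasm, at least 2 px clear of any nucleus
  by default, so every MN is a distinct mask component; a `mn_touching`
  toggle emulates MN lying against a nucleus.
* **Irregular morphologies.** Four modes: overlapping nuclei (centers closer
  than the sum of radii, possibly merging mask components), size mismatch
  (one nucleus at 40–55 % radius), intensity mismatch (one nucleus at
  30–50 % intensity), and irregular shape (elongated elliptical nuclei, axis
  ratio 2.2–3). Any irregular mode forces the truth label IRREG.
* **Noise model.** Separable Gaussian blur (σ 0.6–1.2 px by default) plus
  additive Gaussian noise (SD 2–6 % of full scale) on both channels — the
  simplest model of slightly defocused, sensor-noisy imagery.
* **Easy preset.** `difficulty = "easy"` narrows MN diameter to ≥ 0.20 of the
  nucleus diameter, blur to 0.4–0.8 px and noise to 1–3 %: a well-separated,
  low-noise regime used by the recovery benchmarks. Passing those benchmarks
  shows the pipeline recovers truth under favorable geometry; it does *not*
  demonstrate instrument-grade accuracy on real imagery, which contains
  texture, debris, focus gradients and staining artifacts the generator does
  not attempt.

Nucleus placement uses a jittered ring layout (2–4 nuclei) rather than pure
rejection sampling: it guarantees non-overlapping placement is feasible for
every sampled radius, shrinking nuclei only when geometry forces it, and
raises a placement error after a bounded number of attempts otherwise.
Generation is fully deterministic given the seed: per-object child seeds are
drawn once, so datasets are bit-identical across runs and platforms with the
same RNG.

Dose–response cohorts organize events into `dose / replicate / file`
structure (three data files of 15,000 events per sample is the default file
shape). MN induction applies to BN cells in Cyt-B mode and MONO cells
otherwise; per-dose MONO/BN/POLY mixtures encode cytostasis. Cohorts can be
generated as rendered TIFFs or, for statistics-level work, as label
manifests only (`render = "counts"`).

## Data model and preparation

Images are min–max normalized to [0, 1] **per image and channel**; a flat
image maps to all zeros (the degenerate case is undefined in common
practice; zeros keep downstream arithmetic finite). Per-channel-global
normalization was the alternative; per-image was chosen because acquisition
gain varies object to object on flow instruments.

Ground truth lives in a `gt_store` mapping each class to a set of object
ids; assignment is idempotent and reassignment removes the object from its
previous class, so the six sets are always pairwise disjoint. The
train/validation/test split is stratified per class at 80/10/10. Counts are
rounded by flooring each share and handing leftover objects to the splits in
priority order (train, then validation, then test): a class of 147 splits
118/15/14, a class of 10 splits 8/1/1. Classes need at least 3 members.

Class balancing oversamples each minority class with replacement up to the
majority size (all originals retained); each oversampled duplicate receives
a random dihedral transform, and one additional augmented copy of the whole
balanced set is appended by default. Augmentation is restricted to the six
label-preserving symmetries {identity, rot90, rot180, rot270, horizontal
flip, vertical flip}: these permute pixels, so mask component counts — and
therefore labels — are invariant, which elastic or intensity augmentations
would not guarantee for this taxonomy.

## The classifier

The model is a scaled-down VGG-style stack: three 3×3 same-padding
convolution + ReLU blocks (12/24/48 filters) each followed by 2×2
max-pooling, a 48-unit dense ReLU layer, and a 6-way softmax. The
penultimate layer doubles as the feature extractor for assisted labeling.
Training minimizes cross-entropy with Adam (step 1e-3, batch 32) for at most
70 epochs, stopping early when validation accuracy has not improved for 8
epochs and returning the best-validation weights. The validation and test
splits are never used for weight updates.

All randomness — initialization (He-scaled Gaussians) and per-epoch batch
order — is drawn from R's RNG under the configured seed, so identical
configs and seeds give identical weights; the C++ kernels are
single-threaded and deterministic up to the linked BLAS.

Depth and widths are deliberately modest: the reference architecture family
(16-layer stacks pretrained at ImageNet scale) is config-reachable but not
the default, because the synthetic task is far smaller than instrument-scale
data and a desk machine is the target. At the study scale used in the tests
(~500 cells/class, 64×64 px), training takes a few minutes on one CPU.

## Assisted labeling (cluster / predict)

Building tens of thousands of ground-truth labels by hand is the bottleneck
the assisted workflow addresses. Work proceeds in *segments* of 1500
randomly sampled objects:

* `extract_features()` maps objects through the current encoder's
  penultimate layer (when no trained classifier exists yet, an encoder is
  fitted briefly on the seed ground truth — the package never ships foreign
  pretrained weights).
* `reduce_to_map()` embeds the features in 2D for the object map:
  non-metric multidimensional scaling initialized from classical PCoA.
  NMDS was chosen because it is a seeded, deterministic, nonlinear embedding
  available in the standard ecology toolkit; when labels are supplied,
  within-class distances are shrunk (×0.35) before embedding, a mild
  supervision that pulls labeled classes together.
* `cluster_segment()` over-clusters with k-means at k = 5 × classes
  (capped at the object count). Over-clustering keeps clusters nearly pure
  so whole clusters can be assigned to a class at once. Clustering operates
  on features by default (a flag selects map coordinates instead).
* `predict_segment()` fits a multinomial logistic regression on the
  ground-truth features — the "simple linear model" — and scores every
  object; the maximum posterior is the confidence, and objects below the
  0.5 threshold are labeled UNKNOWN rather than forced into a class. The
  gate requiring ≥ 25 ground-truth members per class must pass before
  prediction is allowed.

`assist_label_loop()` runs this headlessly: high-confidence predictions
(≥ 0.9) enter the ground truth unreviewed; the rest are "manually"
confirmed against the answer key (the manifest truth in tests, a human in
real use). On separable synthetic features the loop reaches ≥ 95 % correct
ground truth with under a quarter of objects manually confirmed.

## Accuracy accounting

`confusion_counts()` tallies per-class TP/FP/FN; UNKNOWN predictions count
as FN for the truth class and FP for none. Precision, recall and F1 are
reported in percent; zero-denominator metrics are *undefined* (NA), never
zero, so they cannot silently drag averages down. The overall model accuracy
is the truth-count-weighted mean of per-class F1 computed from unrounded
values — the only aggregation consistent with all three published overall
accuracies of the reference model whose counts ship in
`reference_confusion_counts()`.

## Assay statistics

Scorable cells are MONO, MONO_MN, BN, BN_MN and POLY; IRREG and UNKNOWN are
excluded from every numerator and denominator. Per file:
`%MN-BN = 100·BN_MN/(BN+BN_MN)`, `%MN-MONO = 100·MONO_MN/(MONO+MONO_MN)`,
plus the BN fraction among scorable cells. A QC flag marks files below the
guideline's minimum of scored BN cells (default 1000).

Cytotoxicity follows TG 487: in Cyt-B mode
`CBPI = (N_mono + 2·N_bn + 3·N_poly)/N_total` (POLY counts 3–4-nucleus
cells; cells with five or more nuclei are rare enough to be out of scope)
and cytostasis is `100 − 100·(CBPI_T − 1)/(CBPI_C − 1)`, undefined when the
control is entirely mononucleated; in non-Cyt-B mode cytotoxicity is
`100·(1 − treated/control)` post-recovery counts. Negative values (treated
outgrowing control) are legitimate and preserved. The `exceeds_limit` flag
uses the upper edge (60 %) of the recommended 55 ± 5 % top-dose band.

Dose–response testing uses the one-sided Fisher exact test (dosed > control)
at α = 0.001, computed as the exact hypergeometric tail — no normal
approximation — and verified against exhaustive enumeration for every table
with margins ≤ 30. Cells are pooled across a dose's replicate files before
testing (the exactness and power argument; a `pool = FALSE` flag tests
per-file and requires every file to reach significance). Replicate
variability is reported as the sample SD of the per-file MN percentages.

## Numerical choices and degenerate inputs

* Flat images normalize to zeros; empty files, empty classes, UNKNOWN as
  ground truth, degenerate Fisher margins and all-MONO CBPI controls raise
  errors rather than returning silent zeros.
* k-means receives multiple starts under a fixed seed; when k would reach
  the number of distinct points, each distinct point becomes its own
  cluster.
* NMDS receives a small deterministic jitter when duplicate feature vectors
  make distances exactly zero.
* Rounding for tabulation is R's `round()` (half-even) at 1 decimal,
  applied only at the reporting edge; all aggregation uses unrounded values.
* The Adam implementation uses the standard bias correction; gradients were
  verified by driving a tiny network to ~zero training loss and by
  batch-vs-single-object equivalence tests.

## Problem sizes used by the shipped checks

The recovery benchmarks use ~3000 easy-mode cells (≈ 500/class, 64×64 px),
split 80/10/10, balanced and augmented to ≈ 5100 training images; training
runs 20–40 epochs in a few minutes on one CPU and reaches ≈ 93–96 %
held-out macro F1. Dose–response checks run at guideline-like scale (3
files × 5000 events per dose) on label manifests. These sizes are the
package's chosen study conditions for a desk machine; they are intentionally
far below instrument scale (hundreds of thousands of events), which is one
reason real-data accuracy cannot be inferred from them.

## Known limitations

* The generator draws smooth geometric cells; real imagery has texture,
  debris, apoptotic bodies, staining variation and focus gradients. Passing
  synthetic recovery shows pipeline correctness, not field accuracy.
* Only dihedral augmentations are used; real-world robustness would need
  richer augmentation and much larger ground truth.
* The linear predict model assumes the encoder features are reasonably
  class-separable; early in labeling (few ground-truth objects) its UNKNOWN
  rate is high by design.
* Trend tests beyond pairwise Fisher (e.g. Cochran–Armitage) are out of
  scope, as are proprietary instrument file formats.
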