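---
title: "Automated thigh-muscle segmentation and fat-fraction quantification: methods"
author: "muscleseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated thigh-muscle segmentation and fat-fraction quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscleseg)
```

## The problem

Fat infiltration of thigh muscle is a marker of severity and progression in
neuromuscular and metabolic disease and in sarcopenia. Fat–water
decomposition (Dixon) MRI separates the water and fat proton signals, so
the per-voxel fat fraction

$$\mathrm{FF} = \frac{F}{W + F}$$

can be computed directly from the two magnitude images. Turning that map
into clinically interpretable numbers requires segmenting the muscles of
interest, and manual whole-volume segmentation of the four functional
groups (quadriceps femoris, sartorius, gracilis, hamstrings — ROI1..ROI4
throughout this package) takes on the order of hours per scan.

`muscleseg` implements a fully automated pipeline: bilateral splitting,
intensity-based removal of subcutaneous fat and skin, a two-channel
slice-wise U-net over the water and fat images, largest-3D-component
postprocessing, fat-fraction quantification, and the evaluation statistics
used to judge such a pipeline — volumetric Dice overlap, percent volume
difference, meanFF difference, scan–rescan ICC, and a one-tailed Welch
test between normal and fat-infiltrated groups.

## Preprocessing

The water image of each thigh half is reduced to a muscle-compartment mask
in four steps:

1. **K-means (k = 2) on the nonzero water intensities** of the whole
   volume; the cluster with the highest centroid is kept. On water images
   muscle is bright while subcutaneous fat is dark, so this removes the
   fat ring. Clustering the whole 3D volume at once (not per slice)
   avoids slice-to-slice threshold jitter. K-means is seeded with multiple
   restarts and the best inertia, so the step is deterministic.
2. **A per-slice binary order-statistic filter** (default 5×5 window,
   rank 7, roughly the 27th percentile of the window) erodes the thin
   residual skin rim. For a binary mask the k-th order statistic reduces
   to neighbourhood counting, which is how it is implemented.
3. **Per-slice hole filling**, which also fills the bone — bone is
   deliberately not removed before segmentation.
4. **An in-plane disc dilation** (default radius 2, Euclidean-distance
   disc) to restore muscle voxels eroded by the previous steps.

The window, rank, dilation element and per-slice-versus-3D choices are not
dictated by any single convention, so all are exposed in
`preprocessConfig()`; the defaults strip a 1–2 voxel rim while preserving
the convex muscle bulk. This intensity-based split assumes the
muscle-dominant regime (muscle FF below roughly 50%); severely infiltrated
muscle whose water signal approaches that of subcutaneous fat would be
misclassified, a known limitation of intensity clustering on water images.

## Segmentation network

The segmenter is a classic U-net operating on 2D slices with two input
channels, water and fat, each independently min–max normalized to [0, 1]
per thigh volume (per-slice normalization is selectable). Each encoder
level applies two 3×3 ReLU convolutions and a 2×2 max-pool with channel
doubling; the decoder mirrors it with nearest-neighbour upsampling, a 3×3
up-convolution, and skip-connection concatenation; a final 1×1 convolution
yields one score map per class. The forward and backward passes are
written in RcppArmadillo (single-precision im2col + GEMM), with Adam
optimization, because the network must train on an ordinary CPU.

Two output heads are available:

* **softmax** (default): 5 classes (background + 4 ROIs) trained with
  categorical cross-entropy;
* **sigmoid**: 4 independent per-ROI maps trained with multi-label
  cross-entropy.

Prediction is the same for both: per-ROI probability maps are thresholded
at 0.5 and pixels above threshold in several maps go to the
highest-scoring ROI. A score of exactly 0.5 counts as background — the
tie-break must simply be deterministic, the case has measure zero. The
softmax default resolves the tension between a categorical training loss
and per-map binarization: the loss is categorical, while prediction
follows the threshold-then-argmax rule.

Training-schedule defaults follow common practice for this task (batch 6,
Adam at 10⁻⁶, 1000 epochs, no augmentation, early stopping available but
off); the desk-scale runs in the tests and the acceptance script override
the schedule (25 epochs at 10⁻³) because the synthetic task converges
quickly. The train/validation split is at the volume level — all slices of
a thigh land in the same side of the split — in roughly 3:1 proportion.

The input spatial size must be divisible by $2^{\mathrm{depth}}$;
violations raise an error instructing padding rather than silently
resizing.

## Postprocessing

Stacked binary predictions can contain spurious islands. For each ROI only
the largest 3D connected component is kept. Default connectivity is 26
(faces + edges + corners): the most permissive choice, so thin oblique
muscles such as the sartorius are not split across anisotropic 6 mm
slices; 6 and 18 are selectable. Connectivity is voxel-topological —
anisotropic spacing is ignored. Ties between equal-sized components are
broken toward the component whose seed voxel comes first in scan order,
making the operation deterministic. `finalizeLabels()` is idempotent and
never increases a ROI's voxel count; both properties are asserted in the
tests with an independent flood-fill oracle.

## Quantification

`fatFractionMap()` computes FF = fat/(water + fat) on the **original**
intensities — never on channels normalized for the network; the pipeline
driver fixes this ordering. Voxels with zero total signal carry no tissue
signal and are excluded from means (and counted) rather than treated as
FF = 0. Per-ROI statistics are the mean FF in percent and the volume as
voxel count × voxel volume.

## Evaluation statistics

* **Dice**: $2|A\cap B| / (|A| + |B|)$ over 3D voxel sets. Two empty
  masks are vacuously in perfect agreement (Dice 1, logged); an empty
  versus nonempty pair scores 0.
* **Percent volume difference**: signed, (auto − manual)/manual × 100;
  absolute values are taken only when averaging over a cohort.
* **meanFF difference**: in percentage points of FF.
* **Repeated scans** of one thigh are averaged per thigh before any
  cohort mean, so rescanned subjects do not dominate.
* **ICC**: single-measure intraclass correlation of the subjects ×
  repeats meanFF table. The default model is ICC(2,1) — two-way random
  effects, absolute agreement — because repositioning repeats are a
  random factor and absolute agreement is what scan–rescan
  reproducibility means; ICC(3,1) is selectable. 95% confidence bounds
  use the standard McGraw–Wong F-distribution construction. A table with
  no between-subject variance is degenerate and flagged rather than
  given a number; a table with zero within-subject variance and real
  between-subject variance returns exactly 1.
* **Group comparison**: one-tailed two-sample Welch t-test (unequal
  variances, Welch–Satterthwaite df), testing whether the infiltrated
  group's meanFF exceeds the normal group's, significance read at
  p < 0.05.

## The synthetic phantom

Real Dixon scans with expert labels cannot ship with a package, so the
pipeline is exercised end to end on synthetic bilateral thigh phantoms
with known ground truth. A phantom cross-section is a set of concentric
structures: a low-intensity skin ring, a fat-dominant subcutaneous ring
(FF 0.9), a muscle compartment carrying four disjoint angular-sector ROIs
(large anterior quadriceps, small medial sartorius and gracilis, large
posterior hamstrings), and a central bone. The signal model is the
simplest one consistent with the FF definition:

$$W = I_t\,(1-\mathrm{FF}_t), \qquad F = I_t\,\mathrm{FF}_t,$$

plus i.i.d. Gaussian noise on both channels, clipped at zero. Noise-free,
every voxel's fat fraction equals its prescribed value exactly, which
gives the quantification module a machine-precision oracle.

Choices a real scan would make differently, and their rationale here:

* **Default grid 64 × 128 × 12 at 1 × 1 × 6 mm** (bilateral): splits into
  64 × 64 thigh halves that a small U-net can train on in minutes on one
  CPU; the full 512 × 512 clinical matrix is supported by configuration.
* **Default ROI fat fractions (0.05, 0.10, 0.20, 0.30)** span normal
  muscle to clearly visible infiltration while keeping water images
  muscle-dominant — the regime both the K-means preprocessing and
  clinical water images operate in.
* **Noise σ = 0.03** of the muscle amplitude: enough to make the task
  non-trivial without modelling any particular scanner; the source
  acquisitions' noise spectra are not characterized, so this is a
  testability choice, not a realism claim.
* **Repositioning** between repeated scans is an in-plane rigid
  transform (≤ 3 voxels translation, ≤ 5° rotation by default) with
  fresh noise — axial acquisition varies in-plane alignment most.
* **Cohort anatomy** varies thigh radius (26–30 mm at phantom scale) and
  fat-ring thickness (5–7 mm) per subject; true FF is drawn uniformly
  from [0.05, 0.4] per ROI.

What the phantom does **not** emulate: MR physics (echoes, T1/T2* bias,
phase errors, chemical-shift effects, multi-peak fat spectra), anatomical
shape variation beyond rigid transforms and radius changes, partial-volume
mixing at tissue boundaries, and inter-rater ambiguity in the ground
truth. Passing the end-to-end criteria therefore demonstrates that the
pipeline machinery is correct and internally consistent — not that the
network would reach the same accuracy on clinical data, which requires
training on real labelled scans at full scale.

## Numerical choices and degenerate inputs

* Min–max normalization of a constant channel maps to all zeros.
* K-means on a constant water field, or with fewer distinct intensities
  than clusters, raises a clustering-degenerate error; an empty mask
  after any step raises an error naming the step.
* Non-finite training loss aborts with a diagnostic reporting the
  learning rate and input range.
* The network core runs in single precision (im2col + SGEMM); parameters
  cross the R boundary as doubles and checkpoints store 17 significant
  digits, so a saved and reloaded model predicts bit-identically.
* All randomness flows from explicit seeds (phantom, cohort, weight
  initialisation, slice shuffling, split); every function restores the
  caller's RNG state, and two runs of `runPipeline()` with the same
  configuration produce identical reports.
* Empty ROIs in evaluation: Dice follows the both-empty = 1 convention;
  ICC tables drop thighs whose repeats lack a meanFF value and flag the
  result as degenerate when fewer than two complete thighs remain.

## Desk-scale study conditions

The acceptance analysis (`scripts/acceptance.R`) and the heavyweight test
train on 20 bilateral phantoms (40 thigh volumes, 6 slices each, 3:1
volume-level train/validation split) and evaluate on 5 held-out bilateral
phantoms, with the reduced U-net (depth 3, 16 base filters, batch 6,
25 epochs of Adam at 10⁻³). These problem sizes were chosen so that the
whole analysis trains and evaluates in a few minutes on a single CPU
while leaving a comfortable margin over the 0.85 mean-Dice bar; a
depth-4/64-filter configuration on full-resolution scans is reachable
through `unetConfig()` without code changes.

## Known limitations

* The intensity-based preprocessing assumes muscle-dominant water signal
  and fails by design for whole-group fat replacement.
* The phantom's geometric regularity makes the segmentation task easier
  than clinical anatomy; desk-scale Dice values are not comparable to
  values obtainable on real scans.
* Multi-stack acquisitions (separate upper/lower thigh stacks) are not
  stitched; inputs are assumed single-stack.
* No bias-field correction and no confounder-corrected PDFF modelling —
  FF here is the plain magnitude ratio.
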