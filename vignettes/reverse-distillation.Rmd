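---
title: "Reverse knowledge distillation for retinal OCT anomaly screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse knowledge distillation for retinal OCT anomaly screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octdistill)
```

## The screening problem

Optical coherence tomography (OCT) produces volumetric scans of the retina as
ordered stacks of cross-sectional B-scans. Screening programs need to flag
volumes showing *any* pathomorphological manifestation — drusen, intraretinal
or subretinal fluid, pigment epithelial detachment, atrophy — without training
a classifier per disease. octdistill approaches this as one-class anomaly
detection: the model is fit on normal scans only, and at test time it scores
how far a B-scan (and, by aggregation, a volume) deviates from learned
normality, together with a per-pixel anomaly explanation map showing *where*
the deviation lies.

## The model

Three convolutional modules cooperate:

* a **teacher** encoder $T$ with $N$ intermediary levels of interest, frozen
  during training, producing feature maps $F_n^T$ of shape
  $(C_n, H_n, W_n)$ with $H_n = H/\mathrm{stride}_n$;
* a **bottleneck** $B$ that projects all $N$ teacher levels to the deepest
  resolution, concatenates them, and fuses them into one compact code
  $F^B = B(F_1^T, \dots, F_N^T)$;
* a **student** decoder $S$ that runs deepest-to-shallowest from $F^B$ and
  emits feature maps $F_n^S$ with exactly the teacher's shapes — the
  "reverse" distillation layout: the student *decodes* a compressed summary
  instead of re-encoding the image.

The per-position disparity between paired feature vectors is a weighted sum of
the cosine distance and the Euclidean distance:

$$
D(f^T, f^S) \;=\; \lambda\!\left(1 -
\frac{f^T \cdot f^S}{\max(\lVert f^T\rVert_2 \lVert f^S\rVert_2,\,
\varepsilon)}\right) + \lVert f^T - f^S \rVert_2 ,
$$

with $\lambda = 1$ and $\varepsilon = 10^{-8}$ by default. Two readings of
this formula are possible (does $\lambda$ weight both terms? is the second
term the norm or its square?); octdistill weights the cosine term only and
uses the unsquared norm, consistent with the subscript-2 notation. Both
choices affect only the relative scale of the two terms.

Training minimizes the per-level spatial mean of $D$, summed over levels:

$$
\mathcal{L} \;=\; \sum_{n=1}^{N} \frac{1}{I_n} \sum_{i=1}^{I_n}
D\!\left(F_{n,i}^T, F_{n,i}^S\right), \qquad I_n = H_n W_n ,
$$

over normal images only, updating the student and bottleneck; the teacher is
structurally excluded from the gradient path (`train_student()` asserts its
checksum is unchanged). Because the student has strictly less capacity than
the teacher (asserted at `model_bundle()` construction) and never sees
anomalies, lesioned regions yield large $D$ at test time.

**Anomaly maps.** Each level's distance map $M_n = D(F_n^T, F_n^S)$ is
bilinearly resized to the input size, the levels are summed, and the sum is
smoothed with a Gaussian kernel (`compose_anomaly_map()`). Per-B-scan maps
are concatenated, in order and without cross-slice smoothing, into a
volumetric map.

**Anomaly scores.** The per-B-scan score aggregates the disparities with
$P = \max$ (a mean option exists); the volume score is the maximum of its
B-scan scores. The max rule scores small drusen-like lesions and large fluid
pockets on a comparable footing, which a global average would dilute.

Two score sources are implemented because the method description does not pin
whether the scalar score is taken before or after resize-and-smoothing:
`per_level_raw` sums per-level aggregates $\sum_n P(M_n)$ of the raw maps;
`composed_map` (the default) applies $P$ to the composed, smoothed map. The
default was chosen because smoothing pools evidence over a lesion's spatial
extent instead of trusting a single feature position, which is markedly more
stable for small lesions at the desk scale this package targets; the raw
variant remains available for ablation.

## The desk-scale backbone

No pretrained ImageNet encoder ships with the package. The default teacher is
a *frozen random* encoder — a recognized variant in distillation-based
anomaly detection — built from non-overlapping patch convolutions
(kernel = stride), so each level halves or quarters resolution in one step:
strides (4, 8, 16) and channels (16, 32, 64) on a 64×64 input give a
16×16×16, 8×8×32, 4×4×64 pyramid. Two initialization choices matter:

* `teacher_lowpass` (default 1): teacher filters are *window-constant* random
  projections — one random draw per channel pair, replicated across the
  spatial window. OCT speckle is per-pixel multiplicative noise; filters that
  pool over their window respond to local anatomy (patch means) rather than
  to noise realizations the student could never predict. With fully iid
  random filters the distillation loss is dominated by that irreducible
  noise and detection degrades sharply.
* `student_width` (default 0.6) and `bottleneck_channels` (default 32): the
  student's hidden widths are a fraction of the teacher's, keeping its
  parameter count strictly below the teacher's while leaving the bottleneck
  code (4×4×32) rich enough to reconstruct normal anatomy precisely. A code
  that is too tight raises the normal-score noise floor and masks small
  lesions.

The student mirrors the teacher with transposed patch convolutions plus
linear 1×1 heads per level. Activations are leaky ReLU (slope 0.1). All
forward/backward passes are exact reshapes plus matrix products; gradients
are verified against finite differences in the test suite.

## Training defaults

Adam with learning rate 2e-2, batch size 2, 20 epochs, cosine learning-rate
decay to zero, and decoupled weight decay 1e-3 (`train_config()`). These were
settled for the desk-scale regime (~200 training slices): the small batch
yields enough optimizer steps within 20 epochs, the cosine decay settles the
student into a sharp minimum, and the weight decay regularizes the decoder
when the training set covers few distinct retinal geometries. A fixed seed
makes the entire run reproducible; `derive_seed()` fans a single master seed
out to per-purpose streams so stages can be re-run in isolation.

## The phantom generator

`phantom_config()` + `generate_volume()` synthesize labelled study data:

* **Geometry.** A stack of `n_layers` horizontal bands between smooth random
  boundaries: a shared tilt/curvature field, per-boundary perturbations with
  correlation length `boundary_smoothness`, and a foveal pit denting the
  inner boundaries toward the RPE. Perturbation fields are saturated at two
  standard deviations so rare draws cannot push the retina out of frame —
  near-edge anatomy is not a valid normal slice. Boundaries are strictly
  increasing per column (enforced and tested). Slices of a volume share a
  smoothly varying geometry along the slice axis.
* **Texture.** Band reflectivities alternate dark/bright with a bright
  RPE-like outer band; multiplicative gamma speckle with unit mean and shape
  `speckle_shape` (default 20) covers retina and background alike. The
  background is deliberately included and noisy, because fluid pockets
  resemble background in intensity — a known failure mode worth emulating.
* **Lesions** (`lesion_spec()`): drusen-like `bump` (a boundary displaced
  upward with bright fill), hyporeflective `fluid_pocket` (an ellipse with
  negative intensity shift), and `deformation` (a smooth warp of the whole
  stack). Lesion size is controlled by `target_area`; discretized shapes land
  within ±20% of it for interior placements, a tolerance that is documented
  and tested. Masks record exactly the modified pixels, and per-slice lesion
  areas are recounted from masks.
* **Study sets** (`simulate_study_set()`): normal volumes plus anomalous
  volumes carrying 1–3 lesioned slices each, kinds mixed, target areas drawn
  from {100, 200, 400, 800, 1600} px² — a 16-fold severity range.

What the phantom does *not* emulate: A-scan physics, shadowing and vessel
artifacts, device-specific noise spectra, inter-patient anatomical diversity,
or real lesion morphology. Passing the package's acceptance properties on
phantoms demonstrates that the mechanism — distillation gap localized at
out-of-distribution structure — is implemented correctly and recovers
separations under controlled conditions; it does not certify clinical
performance on real OCT data.

## Evaluation battery

`roc_curve_auc()` sweeps thresholds over the unique observed scores (positive
iff score ≥ threshold) plus a sentinel at +∞, grouping ties; its trapezoidal
area equals the Mann–Whitney concordance, which the tests verify against an
O(n²) oracle. `pr_curve_ap()` computes average precision by the step-weighted
definition (recall increments as weights), not trapezoids. `optimal_cutoff()`
picks the threshold closest to (0, 1) in ROC space, breaking ties toward the
higher threshold so fewer samples are flagged. `loo_ppv_npv()` transfers that
cutoff leave-one-volume-out and reports PPV/NPV per volume, with
zero-denominator ratios reported as missing and excluded from means (counts
logged), and single-class training folds skipped with a warning.
`anomaly_profile()` linearly interpolates each volume's score sequence onto
100 relative positions (exact for knot-aligned inputs) and averages per
class. `severity_scores()` averages map values above a threshold (0 if none
exceed it, so silent slices rank lowest) and correlates them with relative
lesion area by Pearson and Spearman; the threshold comes from
`training_threshold()`, the pixel-weighted mean map value over the normal
training data — the data-driven analogue of an absolute activation cutoff.

## Numerical conventions

* Bilinear resizing is corner-aligned (output corner samples map to input
  corners); pinned by an independent scalar-loop oracle test.
* Gaussian smoothing uses a discrete kernel of radius 3σ with
  reflect-padding; σ = 0 is the exact identity.
* Coordinates are (row, column) with row 1 at the top of the B-scan.
* Images are min-max normalized per image before encoding.
* 8-bit datasets are PNG; the 16-bit mode uses 16-bit TIFF (round-trip error
  ≤ 1/65535); anomaly maps are stored as 32-bit float TIFF stacks with a
  sidecar scale factor, since raw anomaly intensities are unbounded.

## Problem sizes

The package's reference experiment — used by the test suite and by
`scripts/acceptance.R` — trains on 200 normal slices (25 volumes × 8
B-scans of 64×64 pixels) for 20 epochs and evaluates on 25 held-out normal
plus 25 lesioned volumes. The phantom geometry also supports 496×512 slices
to mirror clinical scan formats; the bundled defaults stay at 64×64, the
scale at which the full pipeline runs comfortably on a single CPU.

## Known limitations

* A random frozen teacher is a stand-in teacher design for desk-scale runs;
  with a pretrained natural-image backbone the same pipeline applies, but
  none is bundled.
* Each B-scan is processed independently; no 3D context is used.
* Anomaly maps indicate approximate location, not segmentation-grade
  boundaries; large hyporeflective pockets may be highlighted at their
  deformed rim rather than their interior, since their texture resembles
  background the student reproduces well.
* The severity threshold is interpreted as a map-pixel mean over training
  data (not a mean of B-scan scores); both interpretations are defensible
  and the choice is exposed via `training_threshold()`.
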