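---
title: "Measuring the separability of subtle stroke lesions on CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the separability of subtle stroke lesions on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

Early ischemic stroke is often invisible to the radiologist on non-contrast
head CT, while diffusion-weighted MRI (DWI) shows it within minutes.  If the
infarcted tissue nonetheless carries a *statistical* signature in CT —
a slight attenuation drop, a subtle loss of texture — then a
sufficiently rich quantitative description of the right region should let a
classifier tell infarcted from healthy tissue better than chance.  That
degree of "better than chance", measured as cross-validated classification
accuracy over candidate regions, is what we call **separability**.

`strokesep` implements the full measurement pipeline:

1. **Synthetic cohort generation** — seeded 2D head-CT phantoms with
   injectable, near-invisible lesions (there is no public dataset pairing
   CT with DWI-derived lesion masks, so the pipeline ships its own
   generator as a first-class, tested component);
2. **registration** — coarse rotational then fine affine alignment, so a
   lesion mask drawn on one slice can be projected onto another;
3. **midline mirroring** — estimating the brain's symmetry axis and
   reflecting each region of interest (ROI) across it to obtain the
   contralateral *candidate region*;
4. **radiomic feature extraction** — a transform × texture-class bank of
   930 named features per region;
5. **information-gain screening** — ranking features by how much they
   reduce uncertainty about the infarct label;
6. **classifier harness** — ten classifier families × surviving-feature
   sets × repeated stratified 4-fold cross-validation, summarized as an
   accuracy grid with per-threshold means and a best cell.

Three pairings are evaluated: lesion vs its mirror (the signal), normal
tissue vs its mirror (the negative control — hemispheres of a healthy
brain should *not* separate), and lesion vs normal tissue.

## The phantom model

`phantom_spec()` describes an axial slice: an elliptical skull ring
(700 HU) around a brain of white matter (25 HU) with a cortical
gray-matter band and deep gray nuclei (38 HU) and paired lateral
ventricles (10 HU) tilted toward the midline.  The ventricles matter:
without them the phantom is nearly rotationally symmetric and the tilt of
the midline would be poorly identifiable, as it would be on a featureless
disk.  Everything is mirror-symmetric about a vertical axis by
construction, then perturbed by

* a smooth left/right attenuation ramp with per-subject random amplitude
  (SD 2 HU) — healthy brains are not perfectly mirror-identical;
* a spatially correlated Gaussian noise field: white noise smoothed at
  2 px and rescaled to SD 6 HU.  This reproduces the second-order
  statistics that texture features consume; it does not model CT
  reconstruction physics (no beam hardening, no streaks), which is the
  main respect in which passing tests here do not certify behaviour on
  real scanner data;
* a per-subject pose (rotation within ±4°, horizontal shift within
  ±8 px), recorded as `true_midline` so the midline estimator can be
  validated against ground truth while the pipeline itself never sees it.

Lesions (`lesion_spec()`) are blobs whose radius is modulated by random
low-order angular harmonics.  Injection applies two feathered effects
inside the ROI: blending with a Gaussian-smoothed copy of the slice
(texture loss, default 1.5 px) and an attenuation shift normalized so the
ROI mean moves by exactly `delta_hu` (default −6 HU).  With noise SD
6 HU the default lesion is at contrast-to-noise ≈ 1 — the premise of the
analysis is precisely that the lesion is near-invisible.  Setting
`delta_hu = 0, smooth_sigma = 0` yields the *null cohort* used for
calibration: lesion-labelled and normal tissue are then statistically
identical by construction.

Cohort layout mirrors the study design the analysis assumes: lesion
subjects contribute one slice each; control subjects contribute three
slices each, with lesion-shaped masks resampled from the lesion subjects'
mask library and placed into a control hemisphere (up to 50 placement
retries, then an error).  A 38 + 18 cohort therefore yields 38 + 54 = 92
(slice, mask) records, and the three pairings have 76, 108 and 56 rows.

## Midline estimation and mirroring

`estimate_midline()` searches a grid of (offset, angle) candidates —
default ±20 px × ±10°, refined from a coarse pass — for the line
maximizing the Pearson correlation between the brain-masked image and its
reflection.  Ties prefer the smaller |angle|, then the smaller |offset|.
The estimate comes from the image alone; generator ground truth is used
only in tests.  `mirror_roi()` reflects a mask by nearest-neighbour
inverse mapping (reflection is an involution, so the same map serves both
directions and leaves no holes).  Mirrors are clipped to the brain; a
pair whose mirror loses more than half its area is dropped with a
message.

## Registration

`coarse_register()` scans rotations (default ±15° in 1° steps) and
`fine_register()` refines (tx, ty, θ, sx, sy) by Nelder–Mead — restarted
once from its incumbent to guard against simplex collapse — on normalized
mutual information with 32 intensity bins, the standard cross-modality
similarity metric.  Transforms compose scale → rotate → translate about
the image centre, row-major, 0-based.  The optimizer never returns
parameters scoring below its initialization; hitting the iteration cap
(500) returns best-so-far with a warning flag.  On noise-free phantoms
the harness recovers known affines within 1 px / 1° / 0.02 scale.

## The feature bank

Per region, ten images are formed — the original; four single-level 2D
Haar subbands (upsampled back by pixel replication); square, square root,
logarithm and exponential of shift-normalized intensities; and the
central-difference gradient magnitude — and each is summarized by 18
first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features
under their standard radiomics definitions: 10 × 93 = 930 features named
`<transform>_<class>_<Feature>`.  The bank's composition is an explicit
registry (`feature_registry()`), configurable in both axes.

Numerical conventions worth knowing:

* transforms are computed on the ROI bounding box padded by 8 px, then
  masked — enough context for the wavelet and gradient, while pixels
  beyond the pad cannot influence any feature (a property the tests
  assert);
* pointwise transforms first shift ROI intensities to ≥ 1 (HU are
  negative) and scale to (0, 1], so the logarithm is defined and the
  exponential cannot overflow; transformed ROI values are then linearly
  mapped back onto the original ROI range so that one discretization
  rule serves all transforms;
* discretization defaults to a fixed 5 HU bin width (robust to the area
  difference between a lesion and its clipped mirror), capped at 64
  levels; a fixed-bin-count mode is available;
* GLCM/GLRLM use the four 2D directions at distance 1 and average
  features over directions; GLSZM zones are 8-connected; GLDM dependence
  counts equal-level 8-neighbours (size = neighbours + 1); a constant
  ROI yields Ng = 1 with the conventional degenerate values (GLCM
  correlation 1, entropies 0);
* non-finite feature values are replaced by 0 (and counted in an
  attribute) so tables stay rectangular.

Shape features are deliberately absent: a mirror is congruent to its
source by construction, so shape would carry no signal in the mirror
pairings and would leak the subject's group in lesion-vs-normal.

Every feature class is verified against an independent brute-force
implementation (explicit pair/run/zone/neighbour enumeration with scalar
loops) to 1e-9 on randomized small ROIs.

## Information-gain screening

For binary infarct label $Y$ and binned feature $X$,

$$H(Y) = -\sum_y p(y)\log_2 p(y), \qquad
IG(X, Y) = H(Y) - \sum_x p(x)\, H(Y \mid X = x).$$

Features are binned by equal-frequency quantiles (k = 10 by default; ties
at an edge go to the lower bin).  There is no canonical choice of k for
tables this small, so it is exposed as `k_bins` and tested at
k ∈ {2, 5, 10}.  Base-2
logarithms make H(Y) = 1 bit for balanced classes, which is what puts the
interesting threshold range at 0–0.5.  Survival counts use strict
inequality ("greater than 0.1").  IG is computed once on the full table,
not per CV fold — this mirrors the analysis design the package
implements, and the selection bias it induces is why the null-cohort
calibration matters: with ~930 features and 76 rows, a sizeable number of
pure-noise features clear 0.1 by sampling error alone (the null IG of a
k-binned feature is approximately $\chi^2_{k-1}/(2n\ln 2)$), and the
report's accuracy for the screened null cohort is the honest measure of
how much that biases downstream accuracy.

## The classifier harness

Ten families with fixed, documented hyperparameters
(`classifier_registry()`): multilayer perceptron (nnet, one hidden layer
of 4 units, decay 0.1 — nnet's BFGS cost grows with the square of the
weight count, which rules out wide layers over a 900-feature bank),
CART decision tree, random forest (ranger, 100 trees), AdaBoost.M1 (50
exhaustively-searched decision stumps, implemented in-package), gradient
boosting (xgboost, 100 rounds, depth 3, η 0.1), bagging (10 bootstrapped
unrestricted trees via ranger with mtry = p), Bernoulli naive Bayes
(e1071, on features binarized at their training-fold medians, Laplace 1),
Gaussian naive Bayes (class-conditional SDs floored at 1e-6), RBF SVM
(cost 1), and 5-nearest-neighbours.

`run_cv()` standardizes features with training-fold statistics only,
scores the pooled fraction correct per fold, and averages over all folds
of all repeats; everything is a pure function of the seed.  Splits are
stratified; for the two mirror pairings they are *paired* — a region and
its mirror share a slice, and splitting such siblings across folds leaks
subject identity.  Pairing lesion-vs-normal is imbalanced (38:18), so the
report carries balanced accuracy alongside plain accuracy (plain accuracy
is the primary metric; its chance level there is the majority rate 0.679,
which is the right reference when reading that column).  `run_matrix()`
skips thresholds with no surviving features (NA cells), and because a
single "average accuracy" is ambiguous, the report exposes all three
aggregations: per-threshold means, the mean over filled grid cells, and
per-classifier means.

## Problem sizes and determinism

The distributed test suite runs the full study layout — 38 + 18 subjects
on 512 × 512 phantoms — with 10 repeats of 4-fold CV, evaluating the
classifier grid at the analysis threshold (IG > 0.1) while counting
survivors over the whole 0–0.5 ladder.  `scripts/acceptance.R` uses a
desk-scale version of the same pipeline (12 + 6 subjects, 256 × 256,
5 repeats) so a complete effect-plus-null comparison reruns in minutes.
Both are pure functions of their seeds, and the end-to-end report is
byte-identical across reruns with equal seeds — the suite asserts this.

## Limitations

* The phantom's noise and anatomy are stylized; absolute accuracies
  measured here say nothing quantitative about clinical CT.  What the
  pipeline does establish is *relative* behaviour: a null cohort
  calibrates to chance, an injected subtle effect is recovered, and the
  three pairings order as the design predicts.
* Single 2D slices only; true multiplanar reslicing, 3D texture, and
  deformable registration are out of scope.
* The midline estimator assumes intensity symmetry; it does not detect
  anatomical landmarks (falx), and gross pathology that breaks symmetry
  would mislead it.
* IG screening on the full table is by design (see above); fold-internal
  screening would be the bias-free alternative and is easy to build from
  `screen_features()` + `run_cv()` if wanted.
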