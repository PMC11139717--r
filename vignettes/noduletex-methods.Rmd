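---
title: "Methods: 2D radiomics of part-solid lung nodules with repeated-CV LASSO selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 2D radiomics of part-solid lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Invasive lung adenocarcinomas that contain solid or micropapillary growth
components carry a worse prognosis than those without, and the distinction
matters when planning limited resection. On thin-slice CT, nodules with such
components tend to be more heterogeneous: a larger solid-attenuation portion
and more disordered intra-nodule texture. `noduletex` implements a complete
2D radiomics workflow for this question: quantify the texture of a segmented
nodule cross-section, select the features that discriminate the two groups
under a resampling-stabilized L1 penalty, convert them to clinically legible
cutoff rules, and evaluate how a radiomics read changes human reader
performance on the same cases.

Because the patient cohort this design emulates is not publicly available,
the package ships a synthetic cohort generator as a first-class, tested
module. Every downstream stage runs identically on real data supplied as
NIfTI image/mask pairs with a manifest.

## The synthetic cohort: a stated world

`cohort_spec()` fixes the world the tests operate in:

* **16 positive / 48 negative cases** — the class split of the emulated
  64-patient cohort.
* **1024-pixel matrix, 345 mm field of view** (0.337 mm/px). Tests and the
  acceptance script generate at 192–256 px instead: all 61 features are
  computed inside the ROI and nodule axes (8–40 px) are unchanged, so the
  smaller background canvas is purely a compute scale-down.
* **Intensity modes**: lung background −850 HU, ground-glass −600 HU, solid
  tissue −50 HU, with 30 HU additive Gaussian noise. These place the group
  mean ROI intensities near the scale reported for real part-solid nodules
  (roughly −500 HU for homogeneous ground-glass lesions versus −200 HU for
  lesions with substantial solid portions).
* **Class contrast**: positives have a higher solid-area fraction
  (0.60 vs 0.15) *and* stronger low-pass-filtered speckle (SD 120 vs 40 HU).
  Carrying the contrast through both channels makes first-order features
  (entropy, coefficient of variation) and matrix features (run-length,
  size-zone, co-occurrence) informative at once, which is what the emulated
  analysis observed. By construction positives have higher ROI entropy and a
  more negative coefficient of variation (the ROI mean is negative, so a
  larger relative dispersion pushes CoV down).

A nodule is a rotated ellipse (axes uniform in 8–40 px) filled with
ground-glass attenuation, plus 1–4 solid-intensity disks sized to the
class's solid fraction, plus the speckle field and pixel noise. Everything
is a pure function of `(spec, label, case_seed)`; cohorts derive per-case
seeds from the spec seed.

What the generator does **not** model: lobulated or spiculated margins,
vessels and bronchi, partial-volume effects, reconstruction-kernel texture,
or inter-reader delineation variability. A green end-to-end test therefore
establishes that the pipeline recovers a heterogeneity contrast of this
geometric kind — not that it reproduces clinical performance figures.

## Segmentation surrogate

The emulated workflow used commercial software: a reader drags a rectangle
around the nodule, the tool segments automatically, and the reader corrects
manually if needed. The commercial algorithm is unpublished, so
`segment_nodule()` implements a documented stand-in: Otsu's bimodal split of
the rectangle's intensities, the largest 8-connected component, and hole
filling. One wrinkle is deliberate: part-solid nodules have a *trimodal*
histogram (lung / ground-glass / solid), and a plain bimodal split can lock
onto the ground-glass-versus-solid boundary. The threshold is therefore
estimated on intensities clipped from above at the solid cap (−300 HU,
configurable), which folds the solid mode — unambiguously nodule — into the
nodule side and lands the split on the lung/nodule boundary.
`apply_manual_override()` mirrors the manual-correction step; in the
synthetic pipeline the truth mask plays the corrected delineation, and the
two readers' feature vectors are averaged with `average_readers()`.

## The 61 features

`feature_registry()` fixes the names and order: 10 first-order, 10 GLCM,
16 run-length, 16 size-zone, 5 NGTDM, 4 shape/intensity auxiliaries. The
exact feature list of the emulated software is not public; this registry is
reconstructed from the standard family definitions with all ten
selected-feature names (`LRHGE`, `LZHGE`, `Variance`, `GLN`, `Mean`,
`GLCM:Correlation`, `CoefficientVariation`, `Entropy`, `GLV`,
`MeanIntensity`) present under exactly those names, and is data-driven so a
corrected list slots in without code changes.

Numerical conventions (all configurable via `texture_config()`):

* **Quantization**: 32 equal-width bins over the ROI's HU range. A 32-level
  scale is consistent with the reported quantized means (16–23, cutoff 19.7)
  and entropy values (3.1–3.5, just under `ln 32 = 3.47`).
* **Entropy log base**: natural log by default, base 2 selectable; recorded
  in the extraction config attached to every feature vector.
* **GLCM**: distance 1; directions 0°/45°/90°/135°; symmetric; each
  direction normalized then averaged. **GLRLM**: same four directions,
  features averaged per direction. **GLSZM**: 8-connected zones.
  **NGTDM**: 8-neighborhood restricted to the ROI.
* **Coefficient of variation**: population (n-denominator) SD divided by the
  raw-HU mean — the usual texture-software convention; negative whenever the
  mean HU is negative. `Mean`, `Variance`, `Entropy`, `Uniformity` are
  computed on quantized levels ("Variance" on raw HU would be an order of
  magnitude larger than the reported 121–246 at 32 levels, which is why the
  level scale was chosen); `MeanIntensity`, `SDIntensity`, `Range`,
  `Skewness`, `Kurtosis` on raw HU.
* **Undefined values** (e.g. `GLCM:Correlation` for a constant ROI, NGTDM
  coarseness when all neighborhood differences vanish) are reported as `NA`
  with a warning — never silently as 0.

Every matrix builder is checked in the test suite against an independent
brute-force enumeration written first (200 random images up to 8×8 with up
to 4 levels), plus conservation identities (GLCM sums to 1; run-length and
size-zone matrices conserve the ROI pixel count) and invariance of the
direction-averaged features under 90° rotation.

## Feature selection

`lasso_importance()` runs L1-penalized logistic regression under 10 repeats
of stratified 10-fold cross-validation and counts, over the 100 fits, how
often each feature's coefficient is non-zero. Decisions the source design
left open, resolved here and recorded in the output object:

* **Binomial, not Gaussian**: the outcome is binary, so the penalized
  *logistic* model is the default; a linear-LASSO variant sits behind
  `family = "gaussian"` for sensitivity analysis.
* **Penalty per fold**: each outer fold picks its own penalty by inner
  5-fold cross-validated deviance over a 50-point grid spanning four decades
  below the smallest all-zero penalty, computed on that fold's standardized
  training data. (Whether the original count-of-100 used one penalty per
  repeat or per fold is unstated; per-fold is implemented.)
* **No leakage**: standardization parameters come from the training portion
  of each fold only.
* **Determinism**: repeat *r* uses `seed + r` for its partition; inner folds
  are seeded from (repeat, fold). Identical `(table, seed)` gives identical
  counts bit for bit.

`select_top()` orders by count, breaking ties by mean absolute coefficient
and then name. `fit_radiomics_signature()` refits on the full data at the
median of the chosen penalties (the original's final-coefficient recipe is
unstated; a full-data refit is the simplest reproducible choice) and stores
the standardization, so `radiomics_score()` is
`intercept + Σ βᵢ (xᵢ − centerᵢ)/scaleᵢ`.

## Cutoffs and models

`youden_cutoff()` searches every midpoint between adjacent sorted unique
values, in both directions, for the maximum of J = sensitivity +
specificity − 1. Ties go to higher sensitivity, then smaller absolute
threshold, then the "greater" direction. `binarize()` assigns the threshold
itself by the direction's inclusivity: strict for "greater", inclusive for
"less-or-equal" (so a rule "≤ −1.13" scores −1.13 as positive). The search
is verified against exhaustive enumeration on 200 random instances.

`univariate_logistic()` and `stepwise_logistic()` use maximum-likelihood
fits with Wald inference (the convention of the statistical software the
design emulated). Stepwise is forward entry at p ≤ 0.05 with backward
removal at p > 0.1, iterated to a fixed point, deterministic in the given
candidate order, with a design-rank guard so duplicated or collinear
predictors enter once. Complete separation in a 2×2 screen is flagged and a
Haldane–Anscombe corrected odds ratio reported alongside, rather than
letting a diverging Wald interval pass silently.

`roc_auc()` is the tie-aware Mann–Whitney statistic with a DeLong variance
for the interval (Wald on the AUC scale, clipped to [0, 1]); the reported
interval method is recorded. For binary predictions AUC equals
(sensitivity + specificity)/2 exactly, which the tests assert.

## Reader-study statistics

Discordance for `mcnemar()` is defined on *correctness* — the compared
quantities are the accuracy/sensitivity/specificity of the same readers
across two sessions on the same cases. The exact two-sided binomial test is
used when the discordant total is ≤ 25 (checked against direct
enumeration), the continuity-corrected chi-square above. Metric differences
come with Wald paired-proportion intervals; which interval method the
emulated study used is unstated, so the method label travels with every
result. `compare_auc_paired()` implements the paired DeLong test; identical
placements give p = 1 by convention.

The restriction to positives (sensitivity) or negatives (specificity), the
percentage formatting, and the integer identity
`accuracy·N = sensitivity·N⁺ + specificity·N⁻` are all exercised in the
acceptance suite by reconstructing the emulated study's published 2×2
tables from its printed counts and reproducing every derived value. Where
only marginal counts are printed the reconstruction uses the
minimal-discordance (nested) realization; the one printed McNemar p-value
that is derivable (sensitivity drop 15/16 → 12/16 on 16 positives, p =
0.25) is consistent with exactly that realization.

## End-to-end evaluation

`run_all()` chains the stages and `cv_model_auc()` reports a 5-fold
stratified cross-validated AUC of the *modelling* chain: cutoffs,
univariate screening and stepwise refit are recomputed inside each training
fold, and held-out cases are scored by the fold's model. The top-10 feature
list itself is chosen once on the full table — matching the emulated
analysis, which did not nest its selection — so the reported AUC should be
read as validation of the cutoff-and-model stage, not a fully nested
performance estimate. On the default-strength synthetic cohort scaled to
128 cases the 10-seed median of this AUC exceeds 0.85 (acceptance test).

## Known limitations

* The 61-feature list reconstructs standard definitions; the commercial
  software's exact formulas are unknowable from the source material.
* NIfTI I/O is a minimal hand-rolled NIfTI-1 subset (2D, float64/uint8,
  little-endian) because no NIfTI package is available in the supported
  dependency set; it is cross-validated against an independent Python
  implementation in the tests. Pixel data round-trip bit-exactly; spacings
  are stored in the format's float32 header fields.
* No 3D texture analysis, wavelet/filtered feature classes, reader
  variability modelling, or DICOM support.
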