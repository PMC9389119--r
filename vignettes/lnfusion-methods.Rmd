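---
title: "Methods: rule-based PET/CT + elastography lymph-node classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based PET/CT + elastography lymph-node classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnfusion)
```

## The classification problem

Enlarged intrathoracic lymph nodes are worked up with two complementary
non-invasive modalities before (or alongside) needle aspiration. FDG-PET/CT
images glucose metabolism: malignant nodes tend to show high uptake, but so
do granulomatous diseases (sarcoidosis, tuberculosis) and reactive
lymphadenitis, which makes PET/CT sensitive but unspecific. Endobronchial
ultrasound (EBUS) elastography images relative tissue stiffness as a color
overlay (blue = hard, green/red = soft): malignant nodes tend to be stiff,
and elastography is comparatively specific. `lnfusion` implements the
quantification of both modalities, the fitting of decision cutoffs, and
their rule-based combination.

## Decision model

Each node yields two PET/CT features and two elastography features that
enter the decision rules:

* **SUVmax**, the maximum standardized uptake value over the node
  delineation, with SUV = tissue concentration (MBq/g) / (injected dose
  (MBq) / body weight (g));
* **TLG** (total lesion glycolysis) = SUVmean × MTV, where MTV is the
  volume of delineated voxels at or above an SUV threshold (default 2.5,
  the usual PET positivity criterion) and SUVmean is taken over those same
  voxels so the identity holds by construction;
* **mean hue**, the arithmetic mean of pixel hue over the node ROI on a
  0–180 hue scale, with the stiff (blue) band defined as [145, 180];
* the consensus **grading score** (1 soft … 5 homogeneous hard) from three
  raters reading twice; a rater's final score is their second read, the
  consensus is the majority, or the median when all three disagree.

The decision rules, with the default cutoffs from `rule_cutoffs()`
(SUVmax 7.02, TLG 12.53, mean hue 132.73, grade 3), are:

* **PET/CT positive** iff SUVmax > 7.02 **or** TLG > 12.53;
* **elastography positive** iff mean hue > 132.73 **or** grade > 3;
* **combined positive** iff *both* modalities are positive (AND fusion).

All comparisons are strict, so a node exactly at a cutoff is a negative
call. AND fusion is monotone by construction: the combined specificity is
at least each component's, and the combined sensitivity at most each
component's — the fusion buys specificity (fewer futile punctures driven
by inflammatory PET uptake) at a bounded sensitivity cost. Malignant is
the positive class throughout, and performance is summarized by
sensitivity, specificity, PPV, NPV, accuracy, FPR and FNR as percentages
(`diagnostic_metrics()`), with FNR = 100 − sensitivity and FPR = 100 −
specificity identically.

## Elastogram color quantification

`to_hue_map()` converts RGB to standard HSV hue rescaled to [0, 180);
achromatic pixels get hue 0 by convention. The stiff band [145, 180] is
used verbatim even though pure HSV blue sits at 120 on this scale: the
reported node-level mean hues (roughly 90–165) and the 132.73 cutoff are
only mutually consistent under that convention, which we therefore adopt
and expose as a parameter.

The blue/green/red pixel-count ratios (B/G, B/R) are defined on a
color-*density* axis rather than on hue: each pixel is assigned to the
nearest entry of a 256-entry blue→green→red colormap
(`elasto_colormap()`, HSV-interpolated from 240° to 0°), and the default
bands are blue [0, 49], green [50, 152], red [153, 255]. Only the blue
band is externally specified; the green/red split of the remainder is the
package's published default and is configurable. The vendor's true
palette is proprietary, so this colormap is an explicit stand-in; hence
absolute cutoffs tied to it (mean gray 193.39, and to a lesser extent
mean hue 132.73) are calibration-specific, not universal constants.

`mean_gray()` defaults to a *stiffness index*: the nearest-colormap index
remapped so deepest blue scores 255 and deepest red scores 0. A plain
Rec.601 luma mode is retained for transparency; it was not made the
default because blue (hard) tissue has *low* luminance, which would
invert the expected malignant > benign ordering of the statistic.

Hue averaging is arithmetic, not circular: under this scale convention no
observed values approach the wrap point, and a circular mean would make
the 132.73 cutoff uninterpretable.

## PET quantification

`suv_map()`, `suv_max()`, `suv_mean()`, `mtv()` and `tlg()` implement the
formulas above on a voxel grid with an explicit binary delineation; the
vendor auto-delineation is not reproduced (unpublished), so the MTV
threshold is exposed (absolute SUV 2.5 default; fraction-of-max mode
available). Voxels exactly at the threshold are included. The CT short
axis is the minimum caliper (Feret) diameter of the delineation on the
axial slice of maximal area, computed by rotating calipers over the
convex hull of the pixel *squares* (not centers), which makes an aligned
rectangle measure its exact short side and a circle its diameter to
within one pixel pitch.

## ROC machinery

`roc_points()` places thresholds at midpoints between adjacent distinct
scores (with ∓∞ anchors) and uses the strict positive call
`score > threshold`, matching the decision rules. The trapezoidal AUC
under this construction equals the Mann–Whitney concordance probability,
which the tests verify against a pairwise oracle. Confidence intervals
use DeLong's placement-based variance (distribution-free, the field
standard) with a normal approximation truncated to [0, 1]; degenerate
variance returns a point interval rather than failing.
`youden_cutoff()` maximizes J = sensitivity + specificity − 1 and breaks
ties toward higher specificity, then toward the lower cutoff — the
specificity preference mirrors the clinical motivation of the combined
rule (reducing false positives), and the second key makes the result
deterministic. Univariate screening uses the chi-squared test with
continuity correction when all expected counts are ≥ 5 and Fisher's
exact test otherwise; the multivariable model is an ordinary IRLS
logistic fit (`glm`, tolerance 1e-8, ≤ 100 iterations) with Wald tests,
and complete separation is detected and flagged instead of silently
reporting runaway coefficients. Inter-/intra-observer agreement uses
unweighted Cohen's kappa on the 5-level grading scale.

## The synthetic cohort generator

No raw clinical images are distributed, so the package generates its own
study material. The generator's defaults encode the reference cohort's
structure:

* cohort composition: 59.74% malignant, diagnosis mix proportional to
  the reference table (adenocarcinoma 42/154, nonspecific lymphadenitis
  52/154, sarcoidosis 7/154, …), and the IASLC station distribution;
  with `stratified = TRUE` (default) the class and diagnosis counts are
  fixed largest-remainder quotas, so a 154-node cohort reproduces the
  composition exactly;
* latent mean hue: normal with mean 145.00 (SD 16.16) for malignant and
  119.66 (SD 17.74) for benign nodes, clamped to [0, 180];
* latent SUVmax: normal with mean 11.00 (SD 5.36) for nodes > 1 cm short
  axis and 6.01 (SD 3.53) for ≤ 1 cm, overridden by the granulomatous
  benign subgroups sarcoidosis (13.53, SD 8.37) and tuberculosis (17.57,
  SD 10.89) — the confounders that drive PET false positives; clamped
  at 0.

Clamping (censoring at the physical bounds) rather than
truncation-with-resampling was chosen deliberately: with the malignant
hue distribution, the upper bound sits 2.2 SD above the mean, and
censoring shifts the realized mean by < 0.1 hue units while resampling
would shift it by ≈ 0.6, i.e. censoring preserves the configured means
essentially unchanged, which is the property the calibration tests rely
on.

Values the source material does not specify were fixed once at realistic
levels and documented here: the short axis is lognormal(meanlog log 13,
sdlog 0.35) mm clamped to [4, 40] (≈ 77% of nodes > 1 cm); grading-score
class-conditional probabilities are (0.02, 0.05, 0.12, 0.36, 0.45) for
malignant and (0.30, 0.35, 0.22, 0.10, 0.03) for benign nodes, chosen so
that the dichotomized grade has sensitivity ≈ 0.81 and specificity
≈ 0.87, the reported operating point of the score; each rater read
perturbs the latent grade by ±1 with probability 0.05, consistent with
the reported agreement kappas near 0.9 (used as calibration guidance
only, not asserted as a target).

### Rendering

`render_elastogram()` draws an elliptical ROI (≈ 50% of the frame) and
samples per-pixel hues so the ROI mean equals the node's latent mean hue
to within ±1 unit and, when a target stiff-area ratio is given, so the
stiff-band fraction matches it to within ±0.02. Hue→RGB uses standard
HSV on the half-circle scale, so the quantifier round-trips the
rendering; pixel hues are kept strictly below the 180 wrap point (a
pixel at exactly 180 would re-quantify as hue 0). When a target SAR and
the latent mean are jointly infeasible (e.g. SAR 1 with a soft latent
hue) the SAR constraint wins and the mean saturates. Note that the
rendered frames exercise the *hue* statistics faithfully but are not
driven through the band colormap, so B/G and B/R values on rendered
frames are incidental — a deliberate limitation, since the band features
are validated against loop oracles on random images instead.

`render_pet_voi()` builds an ellipsoidal delineation whose in-plane short
axis matches the node (within one voxel) and sets the central voxel's
activity so the computed SUVmax equals the latent value exactly (the rest
of the node at half the peak, background at a tenth), making the PET
round trip deterministic.

### Deterministic fixtures

`validation_fixture()` (53 nodes) and `model_fixture()` (154 nodes) are
fully deterministic tables whose features, under the default cutoffs,
force the published confusion counts of the two study groups exactly —
including the joint structure (e.g. 19 of the 26 model-group PET false
positives elastography-negative; 4 of 7 sarcoidosis nodes PET-positive).
Feature values sit ≥ 10% away from every cutoff so boundary-convention
changes cannot flip a call. Per-node feature values are synthetic by
construction; only the induced counts are anchored.

### What the synthetic data does and does not show

The generator reproduces class-conditional *marginal* distributions and
printed counts, not real ultrasound or PET physics: no speckle, no
strain-estimation artifacts, no partial-volume effects, no correlation
between hue and SUV beyond what the class labels induce, and rendered
frames use a stand-in palette. Passing tests therefore demonstrate that
the quantification, statistics and fusion arithmetic are correct and
that the pipeline recovers known inputs — they do not re-validate the
clinical performance claims on new data, and fitted cutoffs (Table-style
AUC/cutoff reports from `ln_fit()`) on synthetic cohorts will differ
from the published ones, which depend on the undeposited patient data.

## Problem sizes and numerical choices

The test suite exercises pixel statistics against per-pixel loop oracles
on 100 random images up to 64×64, fusion monotonicity on 1,000 random
cohorts, ROC/AUC against a Mann–Whitney oracle on 100 random score sets,
and the hue calibration on a 5,000-node rendered cohort at 48×48 — sizes
chosen so the whole suite runs in well under a minute while keeping
Monte-Carlo standard errors small (the 5,000-node mean-hue check has a
standard error of ≈ 0.23 hue units). Ratios with empty denominators
return an `Inf` sentinel with a message; undefined predictive values are
`NA` with a message; empty ROIs, masks and single-class label vectors
are errors.
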