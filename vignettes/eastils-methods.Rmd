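---
title: "Digital TILs scoring with eastils: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital TILs scoring with eastils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eastils)
library(dplyr)
```

## The problem

Stromal tumor-infiltrating lymphocytes (sTILs) are scored by pathologists as
the percentage of invasive-cancer stromal area occupied by mononuclear
inflammatory cells. The score predicts response to neoadjuvant chemotherapy in
breast cancer but is read visually and is noisy between observers. `eastils`
implements a fully digital equivalent for H&E-stained sections:

1. per-slide recalibration of the hematoxylin and eosin stain vectors,
   followed by colour deconvolution of the RGB image into per-stain optical
   densities (OD);
2. watershed nucleus detection on the hematoxylin OD channel and a constrained
   5 µm cell expansion;
3. per-cell morphometric and staining features, supplemented by
   neighbourhood-smoothed copies at 25 and 50 µm, fed to a deep feedforward
   classifier that labels every cell tumor / lymphocyte / stromal / other;
4. the easTILs% score within the annotated invasive tumor region,

   easTILs% = 100 × (Σ lymphocyte area, mm²) / (stromal area, mm²),

   with stromal area = invasive-region area − Σ tumor-cell area. All
   lymphocytes inside the region count, so intratumoral lymphocytes are
   included (a deliberate difference from pathologist sTILs%);
5. the cohort-level statistics used to relate the score to pathologic complete
   response (pCR) and event-free survival (EFS).

Because the original whole-slide images are not shipped with the package,
every stage is validated against a synthetic data generator that plants cells
with exactly known geometry, class and staining, plus a cohort simulator with
a specified easTILs% difference between outcome groups.

## Image model and stain recalibration

Tiles follow the Beer–Lambert law: a pixel with stain concentrations $c_h,
c_e$ has OD vector $c_h \mathbf{h} + c_e \mathbf{e}$ and intensity $I = I_0
\cdot 10^{-OD}$ per channel, with $I_0 = 255$ unless a background patch says
otherwise (the source material does not state $I_0$). `rgb_to_od()` floors
intensities at one 8-bit unit so the transform stays finite.

`estimate_stain_vectors()` is a plane-fit (Macenko-style) estimator: pixels
with OD magnitude below 0.15 or within 2 intensity units of white are
excluded; the remaining OD cloud is projected on its top two principal
directions; the 1st/99th percentile extreme angles within that plane become
the stain vectors, and the vector with the larger blue-channel OD component is
labelled hematoxylin (deterministic tie-break). A near-monochrome cloud
(angular spread < 2°) is treated as single-stain — the estimated direction is
assigned to the stain it resembles and the counterpart falls back to the
conventional vectors — and a tile with fewer than 100 informative pixels
raises a typed error so the caller can fall back entirely. Agreement with the
generating vectors is required only up to 5° of angle, not bit-level, since
the reference tool's exact internal thresholds are not published.

## Nucleus detection

`detect_nuclei()` works on the hematoxylin OD channel at a requested pixel
size of 0.5 µm with the standard parameter set: background radius 8 µm
(morphological opening, subtracted), median radius 0 µm (skipped), Gaussian
sigma 1.5 µm, OD threshold 0.1, nucleus area window [10, 400] µm², maximum
background OD 2, cell expansion 5 µm.

Two internals are deliberate implementation choices:

* **Splitting.** Touching nuclei are separated by an *intensity* watershed on
  the masked smoothed OD with a merge tolerance of 0.05 OD. A
  distance-transform watershed was evaluated first and rejected: after 1.5 µm
  smoothing the distance-map saddle between two nuclei planted at sub-diameter
  spacing is shallower than half a pixel, below any tolerance that avoids
  splitting single elongated nuclei, whereas the OD saddle is deep and stable.
* **Boundary refinement.** Thresholding the *smoothed* image inflates every
  nucleus by roughly the kernel width (a 50 µm² disk would measure ~100 µm²).
  Each watershed object is therefore re-thresholded on the background-
  subtracted unsmoothed image at max(0.1, half its own 95th-percentile OD) —
  half-maximum edge localisation, which sits at the true boundary for a
  blurred step edge. Measured areas of planted disks land within a few
  percent, and an 8 µm² disk correctly falls below the 10 µm² floor.

Areas are always pixel counts × (µm/px)² on the detection grid, so changing
the requested pixel size does not bias area accounting; polygons (convex
contours in µm) are carried for interchange, not for area computation.
`expand_cells()` assigns every pixel within 5 µm of any nucleus to its
*nearest* nucleus (exact Euclidean partition computed from per-nucleus
distance transforms; ties to the lower cell id), so cell footprints never
overlap and shared boundaries run along equidistant lines.

## Features and the cell classifier

Per cell: mean/sd/min/max of hematoxylin and eosin OD in nucleus, cytoplasmic
ring and whole cell; nucleus area, convex-hull perimeter, circularity
$4\pi A/P^2$ (clamped to 1; the convex hull avoids staircase bias on
rasterised boundaries), eccentricity from the pixel second moments, max
caliper; and the cell/nucleus area ratio. `smooth_features()` appends, for 25
and then 50 µm radius, the distance-weighted neighbourhood mean of every base
feature with Gaussian weights $\exp(-d^2 / (2(r/2)^2))$ including the cell
itself. The kernel scale $r/2$ is a documented choice — the source names only
the radii — and is isolated in one function.

The classifier is a fully connected feedforward network on these feature
vectors: eight hidden layers (width 64 by default; the width is not published)
with ReLU activations, a 4-class softmax, z-scored inputs, and mini-batch
AdamW capped at 100 iterations (epochs). Training uses input dropout of 0.2
and weight decay 1e-4: the smoothed feature blocks duplicate much of the
per-cell signal with neighbourhood contamination, and without dropout the
network occasionally relies on them so heavily that a tumor cell surrounded by
lymphocytes is confidently mislabelled. Training is exactly reproducible under
a seed, and ties in the posterior are broken by the canonical class order
(tumor, lymphocyte, stromal, other).

Slide-level QC mirrors the published exclusion rule: a slide fails when more
than 10% of its cells are misclassified against the reference labels (exactly
10% passes). In this package the reference is synthetic ground truth; in
practice it was pathologist review — only the rule's semantics are kept.

## Scoring

Cells belong to the invasive region iff their nucleus centroid lies inside it
(closed boundaries: a centroid exactly on the boundary is in; exclusion holes
subtract), and each retained cell's area is clipped to the region raster
before summation — the common digital-pathology convention that avoids double
counting at boundaries. `summarize_areas()` sums clipped areas per class in
mm² (µm² ÷ 10⁶, kept as a separate step so unit errors are testable).
"Lymphocyte area" uses the expanded-cell footprint by default
(`area_basis = "cell"`), since the published accounting tallies the area
occupied by each cell type after expansion; `area_basis = "nucleus"` is a
config switch because the source does not state which was summed, and the
ground-truth comparisons in the tests use the nucleus basis, where planted
truth is exact. Dichotomization is strictly-greater: easTILs% > 19.9 is high
(the previously published optimal cut point), sTILs% > 20 is high.

## The synthetic generator

`generate_tile()` emulates a 20x H&E scan at 0.4986 µm/px. Classes are
separable by construction, since no quantitative per-class morphology is
published: lymphocytes small/round/dark (r ≈ 2.5 µm, OD 0.9), tumor nuclei
large/moderate (r ≈ 6.5 µm, OD 0.5), stromal (fibroblast) nuclei elongated and
pale (eccentricity 0.9, OD 0.35), "other" small dense apoptotic-body-like
fragments (r ≈ 2.3 µm, OD 1.3). Radii are Gaussian truncated at ±2 sd so the
default classes stay above the 10 µm² detection floor; sizes straddling the
floor can be planted explicitly through the morphology parameters. Nuclei are
placed by rejection sampling with a 5 µm edge clearance (≤ 1000 retries per
cell, then an "overcrowded" error); pair mode plants two nuclei at
sub-diameter spacing to exercise watershed splitting. Noise is additive
Gaussian in OD space (sd 0.02) before exponentiation, preserving Beer–Lambert
invertibility; the eosin level inside nuclei drops to 20% of the stromal
level, as chromatin displaces cytoplasmic eosin. These are stand-ins chosen
once for realism — passing tests show the pipeline recovers *planted* truth,
not that it would reach the same accuracy on real tissue with touching cells,
staining artifacts, folds or ink.

`generate_cohort()` uses the reported group medians of pretreatment easTILs%
(36.1 pCR / 14.8 residual disease) as scenario parameters with a lognormal
within-group distribution. The log-scale sd (0.65) was chosen once so the
simulated overall interquartile range (~20.8%) matches the reported cohort
IQR (21.37%). sTILs% is 0.83 × easTILs% (the ratio of the reported means)
plus Gaussian noise with sd 24.5, truncated to [0, 100]; the noise sd was
calibrated on a large sample so the realised Pearson correlation matches the
reported r ≈ 0.606 after truncation. EFS is exponential within outcome group
(median 80/50 months, an invented but plausible contrast) with uniform
administrative censoring at 24–72 months; a 27% subset carries a paired
posttreatment score with a lognormal multiplicative change (median 0.6).

## Statistics

Group comparisons are two-sided throughout (significance 0.05). Mann–Whitney
uses midranks; p-values are exact by enumeration for ≤ 8 untied observations
per group and normal-approximate with tie correction otherwise (identical
inputs give p = 1, flagged). The paired Wilcoxon drops zero differences and is
exact for ≤ 15 informative untied pairs. The 2×2 chi-square is Pearson's
without continuity correction (a flag enables Yates), since the source does
not state the variant. ROC AUC is computed by the Mann–Whitney identity (ties
count ½) with the DeLong structural-component variance and a Wald 95% CI
clipped to [0, 1]; the paired DeLong z-test compares two scores on the same
patients. Survival uses Kaplan–Meier product-limit estimates with the
log-rank test (hypergeometric tie variance, via the survival package).
Logistic models are IRLS fits (tolerance 1e-8, ≤ 50 iterations) with Wald
tests; complete separation (pinned fitted probabilities together with a
diverging standardized coefficient) and collinear covariates are raised as
errors naming the term; the marker-by-treatment interaction is the Wald test
on the product term. Multiple control arms are pooled by a cohort-prep
transform (`pool_control_arms()`), not inside the tests.

## Problem sizes and numerical choices

The validation suite uses 200 × 200 µm tiles (≈ 401 × 401 px) with 65 planted
cells: 8 training tiles for the classifier and 20 evaluation tiles for
detection/classification/score recovery; feature-space classifier experiments
use 2,000 training and 500 held-out cells per class; Monte-Carlo calibration
uses 10,000 null Mann–Whitney replicates (n = 20 per group) and 100 logistic
coverage runs (n = 300); the cohort scenario runs 100 seeds at n = 113
patients. Degenerate inputs have defined behaviour throughout: empty images
give empty cell sets, stromal area ≤ 0 makes easTILs% an explicit error, a
cell's empty cytoplasmic ring yields zero ring statistics, and every source of
randomness flows from a single integer seed (tiles are bit-identical under a
fixed seed).

## Known limitations

* The synthetic tiles have non-overlapping convex nuclei and spatially uniform
  stain; real sections have touching and overlapping cells, tissue folds, ink
  and out-of-focus regions, all of which degrade detection in ways the tests
  cannot measure.
* The classifier is retrained on synthetic labels; the published trained
  weights are out of scope, so cell-level agreement with the original model is
  not claimed.
* Bit-level parity with the reference image-analysis tool (exact watershed
  merges, background rejection internals) is explicitly not a goal; acceptance
  is via ground-truth recovery.
* Whole-slide I/O is out of scope; images enter as calibrated tiles (PNG +
  JSON sidecar), with a reader seam for other sources.
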