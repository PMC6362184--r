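---
title: "Quantifying leaf senescence in OCT B-scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf senescence in OCT B-scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafoct)
```

## The problem

During autumn senescence a deciduous leaf reorganizes its anatomy: the
distinct cuticle / upper-epidermis / palisade layering of a healthy green
leaf degrades, the epidermis–palisade boundary merges into a single
thickened layer, and the optical attenuation of the tissue changes.
Spectral-domain optical coherence tomography (SD-OCT) resolves these layers
non-destructively at micrometre depth resolution, and three quantitative
summaries of its B-scans track the senescence stage:

1. the **attenuation coefficient** — the slope, in dB/µm, of mean
   log-intensity versus depth in the tissue;
2. **SGLDM (gray-level co-occurrence) texture features** of a B-scan region
   of interest, which quantify microstructural homogeneity;
3. **k-NN staging** of leaves from those features, evaluated with
   leave-one-out cross-validated ROC/AUC.

Real leaf scans are not distributed with this package. Instead, `leafoct`
ships a fully parameterized synthetic leaf phantom whose ground truth —
layer geometry, attenuation, heterogeneity contrast — is known exactly, so
every stage of the analysis pipeline can be validated end to end: the
estimators are run on simulated cohorts and compared against the values the
generator was configured with.

## The phantom model

A B-scan is a depth × width matrix of linear intensity; each column is one
A-line. The noiseless mean profile below the sample surface is

$$ I(z) \;=\; \Big[\, b(z) + \textstyle\sum_k A_k\,
   e^{-(z - d_k)^2 / 2\sigma_k^2} \Big]\; 10^{\,\mu\, z / 10}, $$

where $z$ is depth in µm below the surface, $b(z)$ the bulk backscatter of
the layer containing $z$, $A_k$ and $d_k$ the interface peak amplitudes and
depths, $\sigma_k$ the interface width, and $\mu \le 0$ the attenuation
slope in dB/µm. Interface peaks are Gaussian with $\sigma$ tied to the 7 µm
axial resolution (FWHM) of the modelled instrument; the merged
epidermis–palisade interface of the yellow and red presets is broadened to
$\sigma = 4.5$ µm.

Speckle follows the fully developed model: each pixel is an independent
exponential draw whose mean is $I(z)$ times a smooth multiplicative
heterogeneity field. The field is a log-normal transform
$\exp(c\,g - c^2/2)$ of a unit-variance Gaussian random field $g$ with
30 µm correlation length in both axes; $c$ (the *texture contrast*) is the
stage-calibrated knob that makes senescent tissue more heterogeneous.

Two deliberate idealizations are worth spelling out:

* **Unit lateral mean of the field.** The heterogeneity field is
  renormalized to unit mean over the central 100-column analysis window at
  every depth. Laterally averaged A-lines therefore carry *exactly* the
  configured attenuation slope, which cleanly decouples the texture
  calibration from the attenuation ground truth. Real tissue offers no such
  guarantee; on real data the lateral-averaging step only approximately
  cancels lateral structure.
* **Attenuation-compensating peak visibility.** At the stage attenuation
  magnitudes used here (≈ 1 dB/µm) an interface 100 µm deep sits some
  100 dB below the surface peak, i.e. is invisible on a linear-scale
  profile. Layer-peak analysis of the phantom is therefore performed on the
  dB (display-scale) profile, where interface bumps of 10–15 dB are
  prominent; see "Peak detection" below.

The defaults reproduce the modelled acquisition geometry: 813 A-lines ×
750 depth pixels per B-scan at 2.46 µm lateral and 2.665 µm axial pitch
(200 px ↔ 492 µm lateral and 533 µm axial). All validation cohorts in the
test-suite and in `scripts/acceptance.R` use a scaled 256 × 256 geometry
with unchanged pitches — the estimated slope is invariant to frame size by
construction, and a 200-frame stack then fits comfortably in memory.

Stage presets (`leaf_preset`):

| stage  | attenuation (dB/µm) | sub-surface interfaces          | texture contrast |
|--------|--------------------:|---------------------------------|-----------------:|
| green  | −0.78               | 30 µm and 120 µm, σ ≈ 3 µm      | 0.15             |
| yellow | −1.10               | single, 95 µm, σ = 4.5 µm       | 0.60             |
| red    | −1.20               | single, 110 µm, σ = 4.5 µm      | 1.05             |

The attenuation means are the per-stage ground truths the A-scan pipeline
must recover. The texture contrasts are **calibration constants**, chosen
once so that extracted energy decreases and skewness and sum variance
increase monotonically from green to red with every pairwise difference
significant on 30-sample groups, and so that the four-feature k-NN stager
reaches its documented performance bounds on the 44/43/56 cohort. They are
stage-ordering constants of the phantom, not claims about real tissue.

`generate_labeled_dataset` draws per-sample configurations with small
jitter around the presets — multiplicative log-normal jitter with sd 0.04
on the attenuation magnitude and 0.06 on the texture contrast, and additive
Gaussian jitter with sd 4 µm on sub-surface interface depths — so classes
overlap slightly instead of being trivially separable. Each sample gets 24
frames by default; frame $f$ of a stack uses the derived seed
`derive_seed(seed, f)`, so every output is reproducible from one integer.

## The A-scan pipeline

`estimate_attenuation` composes the standard analysis chain:

1. pixelwise mean over the frames of the stack (`average_frames`);
2. mean over the 100 central A-lines (`extract_averaged_aline`);
3. surface location: the global maximum of the normalized linear profile
   after moving-average smoothing (width 5 px) — the surface is the
   strongest specular reflection;
4. dB conversion, `10 log10(I)` (intensity convention — the phantom is
   defined in intensity, so the pair is self-consistent);
5. ordinary least squares of dB value against depth (µm) over the window
   starting 10 px below the surface and extending 320 µm into the tissue
   (`fit_attenuation`), returning slope, intercept and R².

The fit is unweighted OLS via `stats::lm`; the window deliberately skips
the saturated surface reflection. Interface peaks inside the window bias
the fitted slope slightly; with the preset amplitudes the bias is below
0.02 dB/µm for every stage, well inside the ±0.05 dB/µm recovery band, and
it is deterministic — with the field normalization above, the stochastic
scatter of a 200-frame, 100-line estimate is of order 10⁻⁴ dB/µm.

### Peak detection

`detect_peaks` screens local maxima by topographic prominence (height above
the higher of the two valleys separating the peak from higher terrain) and
a minimum separation of 14 µm (twice the axial resolution). Profile
endpoints are never peaks, so a monotone ramp yields an empty set. Two
threshold conventions coexist:

* **linear scale** — prominence ≥ 0.05 of the profile maximum (the
  normalized-A-line convention); used to locate the surface;
* **dB scale** — prominence ≥ 3 dB absolute. On a dB profile spanning
  several hundred dB a fractional-of-maximum criterion is meaningless, and
  after 200-frame × 100-line averaging the residual speckle roughness is
  ≈ 0.03 dB, so 3 dB sits two orders of magnitude above the noise while
  passing the 10–15 dB interface bumps. Layer peaks and thicknesses are
  measured on this scale, where attenuation does not hide deep interfaces.

The green preset shows exactly two sub-surface peaks (epidermis and
palisade tops); yellow and red show exactly one broadened peak — the
merged-layer signature.

## Texture features

`compute_features` implements the SGLDM/Haralick protocol: quantization to
G = 64 gray levels, symmetric co-occurrence matrices at distance 1 for the
0°/45°/90°/135° offsets, features averaged over the four angles, entropies
in bits (log base 2, with 0·log 0 = 0). Thirteen features come from the
co-occurrence matrix — energy, inertia, inverse difference moment,
correlation, variance, entropy, sum average, sum variance, sum entropy,
difference variance, difference entropy, and the two information measures
of correlation. The fourteenth, **skewness**, is first-order: the third
standardized central moment of the raw (unquantized, linear-intensity) ROI
pixels. It stands in for Haralick's rarely used maximal correlation
coefficient, matching the feature set this analysis tradition reports. Sum
variance is centred on sum average (the widely adopted erratum form);
`texture_config(sum_variance_center = "sum_entropy")` restores the original.

Two preprocessing choices define the default (`scale = "db"`) pipeline:

* the co-occurrence matrix is built from the **display-scale (dB) image**,
  as is standard for OCT texture work — speckle statistics on the linear
  scale are dominated by the exponential intensity distribution;
* the mean axial profile is subtracted from the dB ROI first
  (`flatten_depth = TRUE`), the usual attenuation compensation. Without it
  the depth ramp — hundreds of dB across a 200-px ROI at ≈ 1 dB/µm —
  swamps every co-occurrence statistic; after it, the features measure
  heterogeneity. Quantization then uses a fixed ±25 dB range (bin width
  0.78 dB) rather than the ROI min–max, so that absolute heterogeneity
  differences between stages are preserved instead of being rescaled away.

Skewness is always computed from the raw linear ROI, where both stronger
depth attenuation and a heavier-tailed heterogeneity field push the third
moment up — it rises monotonically with stage by construction.

Degenerate ROIs (zero quantization variance) yield `NA` for correlation
and the information measures, carry a `degenerate` flag, and are excluded
from downstream statistics by `batch_features` consumers.

The automatic batch ROI is 200 × 200 px, centred laterally, with its top
edge 10 px below the detected surface — the same offset the attenuation
window uses.

## Staging and evaluation

`knn_predict` is a plain Euclidean k-NN with per-class scores equal to
neighbour fractions; majority ties break by smallest mean neighbour
distance, then by class order. k = 5 by default — small enough for
44-sample classes, odd enough to limit ties; it is exposed everywhere.
`cross_validate` defaults to leave-one-out (appropriate for ~143 samples
and deterministic); standardization parameters are estimated on each
training fold only. Sensitivity and specificity are one-vs-rest per class
and macro-averaged; the ROC pools one-vs-rest scores of all classes across
folds (micro-averaging) and integrates by trapezoid. The headline ROC uses
the four-feature subset {energy, inverse difference moment, skewness, sum
variance}. A macro-averaged ROC is available by applying `roc_curve`
per class.

## Statistics and chlorophyll

Group comparisons use Student's pooled-variance unpaired two-tailed t-test
(`ttest_unpaired`) with significance tiers at 0.05 and 0.001 and no
multiple-testing correction, matching the reporting convention of the
box-plot figures this pipeline reproduces. Degenerate zero-variance input
returns t = 0, p = 1 for equal means and a flagged infinite-t, p = 0
otherwise. Box summaries use type-7 (linear-interpolation) quartiles and
1.5 · IQR whiskers clipped to the data. `total_chlorophyll` evaluates the
two-wavelength linear combination c₁·A(λ₁) + c₂·A(λ₂); the stored default
is the classic 645/663 nm total-chlorophyll pair (20.2, 8.02 µg/ml per
absorbance unit), and both wavelengths and coefficients are configurable —
extract calibrations differ between solvents, and no specific published
coefficient set is claimed.

## Numerical choices and degenerate inputs

* dB floor: `to_db` rejects non-positive values unless given an explicit
  floor; the pipeline floors at `.Machine$double.xmin` (−3076 dB), far
  below any fit window, so zeros above the surface never clip tissue.
* Quantization bins are half-open with the top value folded into the last
  bin; values outside a fixed range clip to the edge bins.
* R² of a zero-variance fit window is defined as 1 (an exact fit).
* Seed derivation keeps every derived seed below 2³¹ − 1.
* LOOCV has no randomness; the stratified scheme takes an explicit seed.

## What the phantom does and does not show

The generator emulates the features the estimators rely on: a bright
surface interface, stage-dependent sub-surface layering, per-stage
exponential depth attenuation, fully developed speckle, and stage-ordered
multiplicative heterogeneity. It does **not** model interferometric
acquisition physics (sensitivity roll-off, dispersion, refraction, the
confocal gate), vascular or stomatal structure, within-leaf spatial trends,
or any biological variation beyond the documented jitter. Passing the
recovery suites therefore demonstrates that the estimators are correct and
well-calibrated under the stated noise model — not that real leaves of any
species will separate as cleanly. The classifier bounds in particular are
properties of the calibrated cohort.

## Problem sizes used in the validation suites

The test-suite and acceptance script run at the scaled 256 × 256 geometry:
50 stacks × 200 frames per stage for attenuation recovery, the 44/43/56
cohort (24 frames per sample) for staging, 30 samples per stage for the
directionality checks, and 2 000 null simulations (n = 12 per group) for
t-test calibration. These sizes keep each suite to a few minutes while
leaving Monte-Carlo error an order of magnitude below every acceptance
band.
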