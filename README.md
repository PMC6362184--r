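# leafoct

Quantitative analysis of spectral-domain optical coherence tomography
(SD-OCT) B-scans of senescing leaves — with a fully synthetic,
ground-truth-known leaf phantom, so the whole pipeline is testable without
access to real scans.

As a deciduous leaf senesces (green → yellow → red), its layered anatomy
degrades: the distinct upper-epidermis and palisade layers merge into one
thickened layer, the optical attenuation of the tissue steepens, and the
B-scan texture becomes more heterogeneous. `leafoct` implements the three
quantitative readouts of that process:

* **Attenuation coefficient** µ (dB/µm): frames of a stack are averaged,
  100 central A-lines are averaged, and the slope of `10·log10(I)` versus
  depth is fit by ordinary least squares over a 320 µm window starting
  10 px below the air/sample surface peak.
* **SGLDM texture features**: 14 Haralick-type features (energy, inertia,
  inverse difference moment, correlation, variance, skewness, entropy,
  sum/difference statistics, information measures of correlation) from
  gray-level co-occurrence matrices of 200 × 200 px regions of interest,
  averaged over the four distance-1 offsets.
* **k-NN staging**: leave-one-out cross-validated k-nearest-neighbour
  classification of leaves from the feature subset {energy, inverse
  difference moment, skewness, sum variance}, evaluated by confusion
  matrix, macro one-vs-rest sensitivity/specificity, and micro-averaged
  ROC/AUC.

The phantom module (`leaf_preset`, `generate_stack`,
`generate_labeled_dataset`) simulates stacks of speckled B-scans per stage
with known layer geometry, per-stage attenuation (−0.78 / −1.10 /
−1.20 dB/µm for green / yellow / red), fully developed (exponential)
speckle, and a stage-calibrated multiplicative heterogeneity field.
Supporting modules provide Student's unpaired two-tailed t-tests with the
p < 0.05 / p < 0.001 tier convention, box-plot summaries, percent-change
tables, two-wavelength total-chlorophyll computation, multi-page float-TIFF
stack I/O with JSON sidecars, and an end-to-end driver (`run_all`).

The methods vignette (`vignettes/leafoct-methods.Rmd`) documents the model,
every tunable parameter, and the design decisions.

## Worked example

```r
library(leafoct)

## a green-leaf phantom stack at scaled 256 x 256 geometry
cfg   <- leaf_preset("green", n_alines = 256, n_depth_px = 256, seed = 1)
stack <- generate_stack(cfg, n_frames = 200, seed = 1)
estimate_attenuation(stack)
#> <attenuation_fit> slope -0.7898 dB/um (R^2 0.9983, 120 points, rows 52-171)

## a small labeled cohort: texture features and staging
ds  <- generate_labeled_dataset(8, 8, 8, seed = 42,
                                n_alines = 256, n_depth_px = 256)
tab <- batch_features(ds)
fs  <- c("energy", "inverse_difference_moment", "skewness", "sum_variance")
aggregate(tab[, fs], by = list(stage = tab$label), mean)
#>    stage  energy inverse_difference_moment skewness sum_variance
#> 1  green 0.04314                     0.498     13.2         4.94
#> 2    red 0.00906                     0.488     20.6       111.05
#> 3 yellow 0.01617                     0.495     15.5        35.85

cross_validate(tab[, fs], tab$label, k = 5, features = fs)
#> <classification_result> loocv, k = 5
#>         predicted
#> true     green red yellow
#>   green      8   0      0
#>   red        0   8      0
#>   yellow     0   0      8
#> accuracy 1.0000 | macro sensitivity 1.0000 | macro specificity 1.0000 | AUC 1.0000
```

The recovered slope (−0.7898 dB/µm) sits within 0.01 dB/µm of the
configured green-stage ground truth (−0.78); energy falls and skewness and
sum variance rise from green to red, and even this 24-sample cohort stages
perfectly.

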