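Package: leafoct
Title: Quantitative SD-OCT B-Scan Analysis of Leaf Senescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of spectral-domain optical
    coherence tomography (SD-OCT) images of senescing leaves. Provides a
    layered, speckled leaf-phantom simulator with known ground truth
    (interface geometry, exponential depth attenuation, multiplicative
    heterogeneity), an A-scan pipeline (frame and lateral averaging,
    smoothing, normalization, peak detection, layer thickness, and
    attenuation-coefficient estimation by linear fitting of the dB depth
    profile), spatial gray-level dependence matrix (SGLDM/GLCM) texture
    features of B-scan regions of interest, k-nearest-neighbour staging of
    leaves with cross-validated ROC/AUC evaluation, group-comparison
    statistics, and two-wavelength total-chlorophyll computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    class,
    withr
Config/testthat/edition: 3
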