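Package: quspred
Title: Quantitative Ultrasound Prediction of Tumor Response to Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-parameter quantitative ultrasound (QUS) analysis of raw
    radiofrequency (RF) echo data for monitoring breast tumor response to
    neoadjuvant chemotherapy. Implements reference-phantom spectral
    normalization, attenuation estimation and correction, linear spectral
    fits (midband fit, spectral slope, spectral intercept), Gaussian
    form-factor backscatter fits (average scatterer diameter and acoustic
    concentration), Burg autoregressive estimation of spacing among
    scatterers, baseline-normalized feature tables, k-nearest-neighbor
    response classification with leave-one-patient-out evaluation and
    exhaustive feature-subset search, and Kaplan-Meier/log-rank survival
    comparison. A point-scatterer RF simulator with known ground truth
    makes every estimator testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
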