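Package: torreyanir
Title: Portable Near-Infrared Calibration of Protein Content in Nut Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric calibration pipeline for predicting protein mass
    fraction in Torreya grandis kernels from portable near-infrared (NIR)
    diffuse-reflectance spectra (1000-1650 nm). Provides a synthetic-spectra
    generator emulating the three kernel states (in-shell, deshelled,
    granules), the standard spectral preprocessing operators (Savitzky-Golay
    smoothing and derivatives, SNV, MSC, min-max/vector normalization, linear
    baseline correction) and their chains, two-stage outlier screening
    (PCA-score Mahalanobis distance with a robust median + 3*MAD gate, then
    concentration residuals against a 0.4% gate), deterministic SPXY
    calibration/prediction splitting, NIPALS partial least squares regression
    with one-standard-error latent-variable selection, and the full model
    evaluation suite (Rc2, RMSEC, Rp2, RMSEP, RPD, RER) with Kjeldahl
    reference-chemistry utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
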