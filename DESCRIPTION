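Package: ramandx
Title: Chemometric Diagnostics for Raman Microspectroscopy of Biofluids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnostic classification of biofluid Raman
    microspectroscopy maps. Provides a synthetic hyperspectral cohort
    simulator (Lorentzian/Gaussian band models, fluorescence baselines,
    multiplicative gain, cosmic-ray spikes, patient-level random effects),
    raw-map reduction (unfolding, block averaging, spike removal), three
    standard preprocessing chains (Savitzky-Golay smoothing with weighted
    least-squares baseline correction and vector normalisation, extended
    multiplicative scatter correction, first derivative), PCA and NIPALS
    partial least squares factor models, four discriminant classifiers
    (PCA-LDA, PCA-QDA, PCA-SVM with radial kernel, PLS-DA), a 10-fold
    cross-validation harness reporting accuracy, sensitivity, specificity
    and F-score, and spectral biomarker identification by the
    difference-between-mean spectrum combined with PC1 loadings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
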