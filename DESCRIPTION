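Package: nirsoiln
Title: Near-Infrared Calibration of Soil Nitrogen with PLS, SPA-MLR and CARS
Version: 0.1.0
Authors@R: person("NIR Soil", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale chemometrics pipeline for predicting soil nitrogen
    content from near-infrared (900-1700 nm) diffuse-reflectance spectra.
    Provides a synthetic-spectra generator emulating three soil archetypes
    (black soil, loess, calcium soil) under four drying treatments,
    Savitzky-Golay smoothing, SPXY sample-set partitioning on the joint
    spectral-concentration distance, and three calibration routes: full-band
    partial least squares with RMSECV latent-variable selection, successive
    projections algorithm variable selection followed by multiple linear
    regression, and competitive adaptive reweighted sampling followed by
    partial least squares. Models are assessed by the correlation
    coefficient, root mean square error and residual predictive deviation
    (RPD), with conventional RPD quality bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
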