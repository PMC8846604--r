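Package: ustrain
Title: Spatiotemporal Bayesian Regularization for Ultrasound Cardiac Strain Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lagrangian cardiac strain estimation from radio-frequency (RF)
    ultrasound using multi-level 2-D normalized cross-correlation block
    matching with Bayesian regularization of the correlation surfaces.
    Correlation surfaces are treated as probability densities and regularized
    with information from spatial neighbours (SBR) or from a spatiotemporal
    neighbourhood over four consecutive RF frames (STBR-1, STBR-2).
    Includes a synthetic RF speckle phantom with prescribed motion and noise
    for validation, least-squares Lagrangian strain tensors with
    radial/longitudinal decomposition over a segmented myocardial mesh, and
    evaluation statistics (strain bias, normalized strain error, total
    temporal relative error, elastographic SNR and strain-filter curves).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
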