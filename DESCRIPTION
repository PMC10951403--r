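Package: texgeom
Title: Texture Statistics, Calcium-Imaging Responses, and Perceptual
    Discriminability in Mouse Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking higher-order image statistics to mesoscale and
    single-cell visual-cortical responses and to perceptual discriminability.
    Implements stimulus normalization and phase-scrambled spectrally matched
    controls, a complex steerable-pyramid decomposition with Portilla-Simoncelli
    texture statistics and per-group dimensionality reduction, dual-wavelength
    widefield preprocessing with hemodynamic correction and d-prime maps,
    two-photon trace preprocessing with ridge encoding models and
    variance partitioning, representational-geometry and population-decoding
    analyses, and signal-detection analysis of go/no-go behavior. A synthetic
    data module generates every input with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
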