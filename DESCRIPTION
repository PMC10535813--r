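Package: chromaderm
Title: Optical Decomposition and Numerical Modification of Skin Pigmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Physics-based discrimination and modification of skin pigments in
    cross-polarized photographs. A two-layer Kubelka-Munk tissue model renders
    melanin, hemoglobin and shading maps to linear-RGB skin images through a
    spectral illuminant/sensor pipeline baked into a reflectance lookup table.
    A small residual encoder-decoder network, trained self-supervised against
    this differentiable renderer, inverts the model to per-pixel pigment maps.
    Maps can be shifted or scaled with numerical control and re-rendered, and
    the result is quantified with the individual typology angle (ITA) and
    melanin/erythema indices, including region-versus-surround contrast. A
    seeded synthetic-skin generator provides labelled data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
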