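Package: goldpick
Title: Conditional-GAN Detection of Immunogold Particles in Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated annotation of colloidal gold particles in electron
    micrographs, built around a pix2pix-style conditional generative
    adversarial network that translates image tiles into particle masks.
    Includes a U-Net generator and patch discriminator trained with an
    adversarial plus L1 objective, tile planning and stitching for images of
    arbitrary size, connected-component particle extraction with exact
    one-dimensional size clustering, a classical threshold-area-circularity
    baseline detector, detection evaluation (optimal one-to-one matching,
    accuracy, center RMSE, size confusion), CSV and overlay export, and a
    synthetic freeze-fracture-replica image simulator with exact ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
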