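Package: rvmist
Title: Multimodal Intrinsic Speckle-Tracking with Rapidly-Varying Dark-Field
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for speckle-based phase-contrast X-ray imaging (SB-PCXI).
    Reconstructs a sample's diffusive dark-field (effective diffusion
    coefficient), phase-shift, and attenuation maps from matched
    reference-speckle and sample-reference-speckle image pairs by inverting
    the paraxial Fokker-Planck speckle equation without assuming the
    dark-field to be spatially slowly varying. Includes a forward simulator
    with speckle and phantom generators, Fourier-space operators (gradient
    integration, weighted dark-field fusion, inverse Laplacian), a
    Tikhonov-regularised pixel-wise least-squares solver, image-quality
    metrics (SNR, azimuthally averaged power spectrum, cut-off sweep), and a
    command-line pipeline reading TIFF stacks with YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
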