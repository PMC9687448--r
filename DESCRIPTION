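Package: octovessel
Title: Automated Microvessel Detection in Polar-Domain Intravascular OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage detection and quantification of plaque microvessels in
    intravascular optical coherence tomography (IVOCT) pullbacks, working
    directly in the native polar (r, theta) domain. Provides polar-domain
    offset augmentation over a concatenated pullback, the five-step
    pre-processing chain (guidewire/shadow removal, lumen detection, per
    A-line pixel shifting, radial ROI cropping, Gaussian denoising), an
    atrous/ASPP encoder-decoder semantic segmentation network for microvessel
    candidates, a shallow CNN that rejects false-positive candidates from
    30x30 context patches, cross-frame track linking with the consensus
    microvessel definition, and pixel/frame-level evaluation with
    observer-agreement statistics. Includes a seeded synthetic polar-IVOCT
    phantom generator with exact ground truth so the whole pipeline is
    testable without clinical data, and a minimal CNN engine (im2col
    convolution, backpropagation, batch normalization, ADAM) so training runs
    on a plain CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
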