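Package: lashgan
Title: Eyelash Artifact Removal from Ultra-Wide-Field Fundus Images with a
    Jointly Trained Conditional/Unconditional GAN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Removes dark eyelash-shadow artifacts from ultra-wide-field (UWF)
    retinal fundus photographs using a jointly trained adversarial network: a
    U-shaped generator shared between a conditional (paired) and an
    unconditional (unpaired) adversarial objective, followed by a U-shaped
    background refinement module. Includes a synthetic fundus-phantom and
    eyelash-stroke simulator that produces paired and unpaired training data
    with ground-truth artifact masks, a self-contained convolutional network
    engine with explicit backpropagation, image-quality metrics (PSNR, SSIM,
    and the equivalent number of looks over artifact regions), tiled inference
    for large frames, and ablation tooling over the model's sub-networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
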