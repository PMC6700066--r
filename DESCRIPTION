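Package: semsr
Title: Super-Resolution of Scanning Electron Micrographs with a
    Generative Adversarial Network
Version: 0.1.0
Authors@R: person("SEM-SR", "Developers", role = c("aut", "cre"),
    email = "semsr@example.org")
Description: Toolkit for deep-learning resolution enhancement of scanning
    electron microscopy (SEM) images. Simulates gold-on-carbon-like test
    specimens and their low/high-magnification acquisition pairs (including
    aliasing, beam blur, shot noise and beam-damage deformation),
    co-registers image pairs with Lanczos upsampling, correlation-based
    affine alignment and pyramid elastic refinement, prepares normalized
    training patches, trains a U-Net generator against a VGG-style
    discriminator with a composite L1 + total-variation + least-squares
    adversarial loss, and quantifies resolution gain with particle
    gap-resolvability statistics and radially-averaged power spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    digest,
    png,
    optparse,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
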