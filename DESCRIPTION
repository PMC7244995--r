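Package: VidVAE
Title: Privacy-Preserving Variational Autoencoding of Clinical Motor-Task
    Videos with Rater-Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A per-frame variational autoencoder for clinical motor-task
    videos: a densely-connected convolutional encoder predicts a latent Normal
    distribution that is reparameterized into a fixed-length privacy-preserving
    code, and a transposed-convolution decoder reconstructs the frame. Training
    uses a multi-scale structural similarity (MS-SSIM) perceptual loss with
    Kullback-Leibler regularization. The package also provides a synthetic
    finger-to-nose video generator with ordinal severity grades (0-4), a
    simulated-rater model, and a rater-agreement toolkit (linearly weighted
    Cohen kappa for intra- and inter-rater agreement, mean rating difference,
    ratable proportion) so that the full encode-decode-rate-agree pipeline can
    be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    png,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
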