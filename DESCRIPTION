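Package: spikeseg
Title: Three-Stage Training of Spiking U-Nets for Biomedical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and training spiking U-Net segmentation networks
    with a three-stage scheme: a conversion-friendly artificial neural network
    (ANN) is trained to convergence, converted to a spiking network (SNN) of
    integrate-and-fire neurons by weight transfer and early-stop threshold
    balancing (SpikeNorm), and then fine-tuned with surrogate-gradient
    backpropagation through time. Includes Poisson rate-coding encoders with
    binary and ternary spikes, segmentation losses (binary cross-entropy, Dice,
    and their weighted combination), a synthetic generator of MRI-like
    hippocampus-crop volumes with NIfTI input/output, and evaluation harnesses
    (slice-wise and subject-wise Dice, output-threshold sweeps, per-layer firing
    frequency reports, convergence comparisons against direct SNN training).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
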