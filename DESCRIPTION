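Package: dualtracer
Type: Package
Title: Simulation and Multi-Task Deep Direct Reconstruction for Simultaneous Dual-Tracer Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end workflow for simultaneous dual-tracer dynamic positron
    emission tomography (PET). Simulates 2D multi-ROI phantoms, generates
    single-tracer dynamic activity images from the two-tissue compartment
    model with randomized kinetic and plasma-input parameters, forward
    projects them through a strip-integral parallel-beam system matrix,
    adds Poisson counting noise with a uniform randoms background, and forms
    dual-tracer sinograms by summing the single-tracer sinograms. Training
    labels are reconstructed frame-wise with ordered-subsets expectation
    maximization (OSEM). A multi-task 3D convolutional encoder-decoder
    network (one shared encoder, two parallel decoders) reconstructs the two
    single-tracer dynamic image sequences directly from the dual-tracer
    dynamic sinogram, trained with a combined MSE/SSIM loss; MSE, MS-SSIM and
    PSNR evaluation metrics are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'dualtracer-package.R'
    'projector.R'
    'io.R'
    'kinetics.R'
    'nn.R'
    'loss.R'
    'metrics.R'
    'network.R'
    'osem.R'
    'phantom.R'
    'pipeline.R'
    'protocol.R'
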