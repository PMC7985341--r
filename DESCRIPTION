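Package: epiwarp
Title: Simulation, Correction and Assessment of EPI Susceptibility Distortions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying geometric distortions in gradient-echo
    echo-planar imaging (GE-EPI) caused by static-field (B0) inhomogeneity,
    and for correcting them by two standard routes: dual-echo gradient-echo
    (GRE) field mapping and reversed phase-encoding (blip-up/blip-down,
    TOPUP-style) displacement estimation. Includes the distortion forward
    model (field offset to voxel-shift-map conversion, mass-conserving
    warping and unwarping along the phase-encoding axis), a synthetic
    multi-tissue head phantom with ground-truth fields, task activations and
    network fluctuations, a quality-guided phase unwrapper, a regularized
    Gauss-Newton reversed-PE field estimator, and the full set of assessment
    metrics: normalized mean squared error, cross-correlation,
    boundary-based-registration cost, Dice-based resting-state-network
    template assignment, and block-design GLM activation mapping with
    cluster thresholding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'warp.R'
    'nifti.R'
    'functional.R'
    'phantom.R'
    'fieldmap.R'
    'ica.R'
    'metrics.R'
    'topup.R'
    'runner.R'
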