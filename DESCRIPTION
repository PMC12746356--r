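Package: coroflow
Title: Simulation and Quantification of 3D Phase-Contrast Coronary Flow MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and post-processing chain for
    three-dimensional phase-contrast (PC) MRI of coronary blood flow.
    Generates digital flow phantoms (tubular vessels with parabolic
    laminar flow and optional stenoses), simulates four-point
    flow-encoded acquisitions with inter-scan motion, complex Gaussian
    noise and pseudo-random k-space undersampling, and reconstructs and
    analyses them: compressed-sensing reconstruction with wavelet
    regularisation, edge-based translational co-registration, four-point
    velocity decoding, background-phase and flow-displacement
    correction, centerline-based per-slice maximum-velocity
    quantification with ostium pruning, and scan-rescan agreement
    statistics (Bland-Altman, paired t-tests) plus alignment of
    externally supplied FFR traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
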