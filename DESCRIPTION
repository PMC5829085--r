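Package: respicor
Title: Internal-External Respiratory Motion Correlation Modeling for
    Surface-Guided Tumor Tracking
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for surrogate-driven respiratory motion modeling in
    lung radiotherapy. Builds a PCA-based correlation model between the
    deformation vector fields of internal organ surfaces (tumor, lung)
    and an external torso surface sampled on a uniform patch grid, and
    predicts internal surface motion from external surface observations.
    Includes an analytic 4D thorax phantom with sinusoidal breathing
    trajectories and exact cross-phase vertex correspondences, mesh
    voxelization, tracking-accuracy metrics (center-of-mass error, Dice
    coefficient, percent error, Hausdorff distance), and evaluation
    protocols for intra- and inter-fraction tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
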