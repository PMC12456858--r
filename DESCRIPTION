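Package: cordquant
Title: Volumetric Registration and Atlas-Based Quantification of Cervical
    Spinal Cord Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for serial-section fluorescence imaging of the mouse
    cervical spinal cord: construction of symmetric average intensity
    templates by iterative registration and averaging, multistep (rigid,
    affine, b-spline) intensity-based registration driven by a mutual
    information metric on a multiresolution pyramid, landmark (fiducial)
    affine refinement, random-forest pixel classification into 8-bit
    probability maps, and region-specific (cervical level x Rexed lamina x
    hemicord x motor pool) quantification of classified signal with
    nonparametric group statistics (Kruskal-Wallis, Dunn's test, FDR
    correction). Includes a synthetic phantom-cord generator with known
    ground truth so that every pipeline stage can be validated end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    RNifti,
    ranger,
    Matrix,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
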