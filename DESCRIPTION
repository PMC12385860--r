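Package: focusctu
Title: Focused-View Rendering of CT Urography Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Produce "focused view" CT urography: given a contrast-enhanced
    CT urography (CTU) volume, its unenhanced companion scan and a
    urinary-tract segmentation, mask out every voxel outside the kidneys,
    ureters and bladder so that incidental findings in other organs are
    concealed.  Three masking methods are provided: the raw segmentation,
    a millimetre-specified spherical boundary dilation, and boundary
    dilation plus straight-path bridging of interrupted ureter
    segmentations.  The package also contains a synthetic paired-volume
    phantom generator with analytic ground-truth labels, a compact
    trainable 3-D U-Net segmenter with cross-validated ensembling and
    sliding-window inference, affine/rigid registration by
    cross-correlation, and reader-study style evaluation statistics
    (visibility coverage and ordinal scores, diagnostic accuracy tables,
    Cohen's kappa, concealment checks).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
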