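Package: ielec
Title: Intracranial Electrode Localization, Projection, Labeling and Template Warping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless pipeline for locating stereo-EEG and electrocorticography
    electrode contacts from post-implant CT and pre-implant MR volumes: mutual
    information affine CT-to-MR registration with optional manual pre-alignment,
    snap-to-center contact refinement by monotone voxel region growing, brain-shift
    compensation by projection onto a leptomeningeal surface mesh, volumetric
    anatomical labeling against a segmentation and color lookup table, and
    symmetric diffeomorphic warping of contact positions to a template brain.
    Ships a deterministic synthetic head-phantom generator with ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
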