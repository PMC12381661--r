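Package: rootletreg
Title: Rootlet-Based Registration of Cervical Spinal Cord MRI to a
    Straightened Template
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Registers cervical spinal cord MRI volumes to a straightened
    template using dorsal nerve-rootlet landmarks instead of intervertebral
    discs. Provides spinal cord centerline extraction and straightening,
    non-linear rostro-caudal alignment of per-level rootlet centers of mass,
    masked B-spline refinement along the superior-inferior axis, slice-wise
    warp symmetrization, axial cord-size scaling, and displacement-field
    composition and inversion. Includes validation metrics (per-level
    rostro-caudal overlap with template rootlets, slice-wise cross-sectional
    area profiles with normalization and cervical-enlargement localization)
    and a synthetic cervical-cord phantom generator with known ground truth
    for end-to-end testing, plus a disc-landmark baseline for head-to-head
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
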