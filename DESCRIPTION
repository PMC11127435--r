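Package: kinepose
Title: Skeleton Field Synthesis, Multi-Person Pose Assembly, and
    Movement Classification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for 2D human-movement monitoring pipelines built on
    keypoint skeletons. Generates labelled synthetic multi-person skeleton
    motions and renders ground-truth joint confidence maps and part
    affinity fields; recovers per-person skeletons by peak detection,
    affinity line integrals and greedy limb matching; standardizes
    keypoint sequences by range normalization and Procrustes calibration
    with anisotropic per-axis scaling; extracts segment-wise polynomial
    trajectory features with goodness of fit; reduces features by a
    five-stage PCA with strict train/test asymmetry; and classifies
    movement classes with a one-vs-rest support vector machine, reporting
    per-class precision, sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
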