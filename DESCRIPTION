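Package: vertmorph
Title: Vertebral Morphometry and Insufficiency-Fracture Detection on
    Mid-Sagittal Lumbar Spine Images
Version: 0.1.0
Authors@R:
    person("Vertmorph", "Developers", email = "maintainers@vertmorph.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantitative vertebral body
    assessment on mid-sagittal lumbar spine magnetic resonance images:
    slice selection and standardization, a pluggable vertebral-body
    segmentation stage with Dice evaluation, mask post-processing,
    corner-landmark detection by three complementary strategies with an
    overlap-maximizing selector, vertebral morphometry (anterior,
    posterior and central heights, endplate concavity depths, vertebral
    angle), and Genant-rule classification of wedge, concave and crush
    deformities. Includes a synthetic spine phantom generator with
    analytic ground truth so every stage is testable without clinical
    data, and the agreement and diagnostic statistics used in reader
    studies: intraclass correlation, Cohen's kappa, Bland-Altman limits
    of agreement, and sensitivity, specificity and accuracy with exact
    binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
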