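Package: stereosim
Title: Design-Based Stereology Estimators Validated on Synthetic 3D Tissue Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and estimation toolkit for design-based stereology of
    axonal afferents and neuron populations. Generates synthetic 3D scenes
    (fiber fields as polylines, amyloid-type plaques as spheres, neuron
    populations as ellipsoids) with known ground truth, slices them into
    systematically sampled thick sections, and applies the classical
    estimators: spherical ("spaceball") probes for fiber length density,
    plaque-proximity stratification of probes (within/near/distant), the
    optical fractionator for total neuron number, and the vertical nucleator
    for cell size. Group-level statistics (normalization to a control group,
    one- and two-way ANOVA, Tukey/Newman-Keuls/Fisher post-hoc tests) close
    the loop from scene truth to reported percentages, so every estimator can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
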