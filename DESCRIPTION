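Package: spinecouple
Title: Coupled Musculoskeletal and Finite Element Simulation of Lumbar Spinal Fixation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a parametric synthetic thoracolumbar spine (T10 to pelvis),
    solves it as a static finite element model of rigid vertebrae connected by
    generalized bushing joints, tension-only ligament springs and beam-element
    posterior instrumentation, and couples it to an inverse-static
    musculoskeletal stage that calibrates joint rotational stiffness, imposes
    intervertebral rotations and resolves muscle redundancy by convex static
    optimization. Range of motion, T10 reaction moments and pedicle-screw/rod
    von Mises stresses can be computed and compared between simplified loading
    (7.5 Nm pure moments) and realistic loading (muscle forces), for the intact
    spine and for an L1-L5 posterior fixation with pedicle screws and rods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
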