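Package: jumpmech
Title: Biomechanics of Maximum-Speed Sprinting and the Long Jump Take-Off
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing long jumpers with a unilateral
    below-knee amputation to non-amputee athletes from force-plate, motion
    capture and laser-gun records. Provides zero-phase Butterworth filtering
    and stance detection, ground-reaction-force descriptors and between-leg
    asymmetry statistics, centre-of-mass energetics and collision angles,
    link-segment Newton-Euler inverse dynamics with a cuboid-composite
    prosthesis inertia model, ballistic jump-distance and take-off-angle
    computation, and a regression-plus-residual-threshold framework that
    converts differences in horizontal velocity loss during the take-off
    step into a jump-distance advantage. A synthetic-trial generator with
    closed-form ground truth makes every stage testable without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
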