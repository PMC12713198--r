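Package: rotastig
Title: Cyclotorsion-Induced Residual Astigmatism Analysis for Refractive Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alpins vector analysis of astigmatism correction (target-induced,
    surgically induced and difference vectors, angle of error, correction
    index, index of success) in the double-angle plane; a closed-form
    cross-cylinder model of the residual astigmatism left by applying a
    cylindrical correction rotated away from its intended axis; a seeded
    synthetic-cohort generator calibrated to a published SMILE cyclotorsion
    cohort; and the correlation, regression and ROC-threshold pipeline used
    to relate static ocular rotation to postoperative residual astigmatism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
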