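Package: tavrisk
Title: Biomechanical Prediction of Atrioventricular Block and Prosthetic
    Valve Design for Transcatheter Aortic Valve Replacement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates the biomechanics of transcatheter aortic valve
    replacement (TAVR) on a structured hexahedral model of the aortic
    annulus and predicts the risk of post-procedural atrioventricular
    block (AVB). Calcium deposits are virtually displaced and rotated
    against the aortic wall, stent oversizing and calcium protrusion are
    applied as displacement boundary conditions to a small-strain linear
    elasticity solve, and von Mises stresses in the NCC-RCC conduction
    system zone are combined with clinical factors in a regularised
    support vector regression risk model. Includes univariate DX-score
    feature selection, inverse optimisation of prosthetic valve size and
    cylindrical-sector vacancy angle, leave-one-out cross-validation with
    baseline comparators and feature-group ablation, a perturbation
    sensitivity analysis, and a seeded synthetic cohort generator for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    rpart,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
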