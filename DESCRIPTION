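Package: capsulereg
Title: Instantaneous Calibration of Subject-Specific Hip Capsule Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reduced-order modeling of the implanted hip capsule as a
    six-sector sleeve of tension-only nonlinear springs wrapping the femoral
    head, together with the statistical machinery to calibrate it
    instantaneously: a principal-component shape model of the capsule
    attachment ellipses, Latin-hypercube probabilistic trial generation
    linking capsule stiffness and pre-strain to torque-rotation hip laxity,
    stepwise multilinear regression surrogates that predict the twelve
    capsule mechanical parameters from laxity measurements and shape-model
    scores, and a closed-loop validation harness (predict, re-simulate,
    root-mean-square error) with training-size convergence and
    training-set comparison utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
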