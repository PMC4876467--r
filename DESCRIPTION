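Package: tlintcp
Title: Actuarial NTCP Modelling of Radiation-Induced Temporal Lobe Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for normal-tissue complication probability (NTCP)
    analysis of radiation-induced temporal lobe injury after
    intensity-modulated radiotherapy. Extracts dose-volume-histogram (DVH)
    metrics (Dmax, DxCC, Vx, mean/median dose), screens correlated
    dosimetric predictors with an elastic-net-penalized Cox model fitted by
    cyclic coordinate descent under patient-level cross-validation, fits
    univariate Cox and logistic dose-response models, inverts them into
    tolerance-dose tables with delta-method standard errors, and computes
    Kaplan-Meier actuarial incidence and cohort comparison statistics. A
    synthetic bilateral-cohort generator with known ground truth supports
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
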