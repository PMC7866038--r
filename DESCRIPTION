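Package: etscc
Title: Estimated Tumor-Site Chemotherapy Concentration for Colorectal Liver Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the time-averaged 5-fluorouracil concentration reached
    inside colorectal liver metastases (eTSCC) from routinely collected
    clinical inputs: a two-compartment plasma pharmacokinetic model of
    bolus-plus-infusion dosing over multiple chemotherapy cycles, a tumor
    blood volume fraction surrogate derived from three-phase CT Hounsfield
    unit measurements, and a diffusion-limited drug penetration model based
    on modified Bessel functions.  Includes a logistic-regression responder
    classifier with ROC analysis, accuracy-maximizing threshold selection and
    leave-one-out cross-validation, a proportional-odds model for clinical
    covariates, and a synthetic cohort generator so the full pipeline can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    Matrix,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
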