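Package: skincal
Title: Skin Calorimetry Modelling of Localized Muscle Heat Flux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for skin calorimetry in exercise physiology: a two-body
    conduction model of a skin calorimeter, calibration of its thermal
    parameters from excitation records, inverse reconstruction of skin heat
    flux and subcutaneous temperature, estimation of skin thermal resistance
    and heat capacity from thermostat steps, fitting of a two-exponential
    response model with a linear-exponential transient term to exercise and
    recovery heat-flux traces, and derivation and simulation of a
    subject-specific transfer function that predicts the heat-flux response
    to arbitrary mechanical-power protocols. Includes a synthetic-data
    generator that emulates full measurement sessions from known ground
    truth so every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
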