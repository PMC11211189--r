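Package: eproximetry
Title: EPR Oximetry Analysis of Tumor Oxygenation After Photodynamic
    Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for electron paramagnetic resonance (EPR) oximetry in
    preclinical photodynamic therapy (PDT) studies: simulation and fitting
    of first-derivative Lorentzian EPR lineshapes, conversion between
    peak-to-peak linewidth and oxygen partial pressure via a lithium
    phthalocyanine (LiPc) calibration line, tumor growth analysis
    (ellipsoid volumes, responder classification, time to progression),
    evaluation of oxygenation-change biomarkers of treatment outcome
    (through-origin regression, predictor fractions, Kaplan-Meier medians
    and log-rank tests), and a seeded synthetic cohort generator that
    emulates the animal groups of a chlorophyllide-PDT melanoma study so
    that the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
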