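Package: uhicoral
Title: Underwater Hyperspectral Classification of Cold-Water Coral Exposure Status
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess the health and toxicant-exposure status of the
    cold-water coral Lophelia pertusa from underwater hyperspectral imagery.
    Implements radiometric reflectance calibration against a Spectralon panel
    and an inclined PVC reference plate, extraction of labelled pixel spectra,
    dose-response (LC5/LC25) categorisation of 2-methylnaphthalene exposure with
    bootstrap confidence intervals, and a standardise -> partial-least-squares ->
    nu-support-vector-machine classification pipeline with per-organism majority
    voting. A synthetic tank-scene generator with known ground truth makes the
    full pipeline testable end to end without access to raw survey imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    rhdf5
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
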