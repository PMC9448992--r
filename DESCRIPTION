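Package: tpdiscrim
Title: Two-Point Discrimination Modeling for Epiretinal Prostheses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the spatial resolution of epiretinal prosthesis users from
    two-point discrimination psychophysics. Builds spiral retinal axon-bundle
    trajectories around the optic disc and computes physical, to-axon and
    along-axon distances between electrodes of a 6x10 epiretinal array; fits
    logistic models of the probability of reporting two percepts with nested
    likelihood-ratio tests, fixed-weight augmentation and iso-performance
    inversion; and simulates disk-electrode current spread on the retinal
    plane with a midpoint "dip" statistic, parameter sweeps, contour matching
    against regression predictions, and lift/damage ablations. Includes seeded
    synthetic-data generators emulating the trial structure of the
    psychophysical task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
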