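Package: carrionfate
Title: Carcass Fate and Biomass Attribution for Urban Scavenger Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for camera-trap carcass-fate experiments with facultative
    vertebrate scavengers. Converts per-image detection records into
    behavioural observations, classifies them as diurnal or nocturnal from
    computed sunrise and sunset times, estimates circular kernel-density
    activity curves, and partitions control-adjusted carcass biomass loss
    among scavenger species using feeding-time by body-mass weights, with a
    calibrated in-situ consumption rate to split pre-removal feeding from
    whole-carcass removal credit. Includes a stochastic study simulator with
    a hidden ground-truth consumption ledger for validating every stage of
    the pipeline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
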