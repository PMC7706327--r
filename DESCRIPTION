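Package: rhizocore
Title: Virtual Soil Coring and Coring-Strategy Evaluation for Root Phenotyping
Version: 0.1.0
Authors@R: person("rhizocore", "maintainers", email = "rhizocore@example.org",
    role = c("aut", "cre"))
Description: Simulates contrasting maize and common-bean root system
    architecture phenotypes in four-plant plots, performs virtual soil coring
    at the six standard field coring locations, estimates whole-plot root
    length density profiles by Voronoi-area weighting, and evaluates coring
    strategies via TOST equivalence testing, rooting-depth quantiles,
    resampling power analysis, and quadratic discriminant classification.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
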