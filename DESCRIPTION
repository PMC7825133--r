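Package: deploysim
Title: Receiver-Station Deployment Simulation for Passive Animal Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of passive telemetry deployments. Animals
    move under a discrete-time central-place stochastic model; attached sensors
    buffer one data package per time step and flush their memory to a receiver
    station whenever the animal enters its reception radius. The package
    characterises the data-transfer function (mean transmitted packages per
    unit time per animal) under random, at-home and mobile station placements,
    computes R90 and inter-event-time statistics, fits saturating-exponential
    transfer laws, and applies the same evaluation to geographic trajectories
    using great-circle distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    geosphere,
    optparse,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
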