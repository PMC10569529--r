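Package: polarsim
Title: Particle-Based Stochastic Simulation of the Yeast Mating Polarity Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Particle-based stochastic reaction-diffusion simulator for the
    Cdc42 polarity circuit of budding yeast during mating, together with its
    quantification stack. Simulates the core Bem1-GEF positive-feedback
    circuit, the receptor-Far1 circuit, their combination, and a
    pheromone-binding variant, by Brownian dynamics of point particles on a
    periodic plane or on a sphere with a cytosolic interior. Includes a
    normalized Ripley's K polarity statistic, polarity-regime classification
    from bimodal K distributions, Voronoi-tessellation cluster detection with
    negative-control threshold calibration, cluster-dynamics statistics
    (occupancy, transitions, dwell times), an extracellular pheromone field
    between an emitter and a receiver cell, and synthetic point-pattern
    generators for testing every analysis step without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deldir,
    graphics,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp,
    dqrng,
    BH,
    sitmo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    spatstat.geom,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
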