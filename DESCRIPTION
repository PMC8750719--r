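Package: dropsolid
Title: Three-Stage Solidification Model for Sprayed Food Droplets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Lumped-capacitance simulator for the solidification of small
    liquid droplets sprayed into cold air, as used in spray crystallization
    of confectionery fats such as cocoa butter. A droplet passes through
    three stages: sensible pre-cooling of the liquid, a phase-change stage
    in which latent heat is released while a solid shell grows inward, and
    tempering of the fully solid particle towards the ambient temperature.
    Convective heat transfer is closed with the Ranz-Marshall correlation
    using temperature-dependent air properties. The package provides
    event-located ODE integration of the staged model, an apparent-specific-
    heat comparator that demonstrates the classical latent-heat
    under-release of that method, an optional well-mixed local gas cell for
    droplet-gas thermal coupling, packaged validation scenarios, a
    parametric sweep over droplet size, ambient temperature and drop-gas
    velocity, exponential correlation fitting of the stage durations, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
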