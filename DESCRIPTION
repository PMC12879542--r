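Package: crystalpbe
Title: Discrete-Method Population Balance Simulation of Batch Cooling
    Crystallization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates seeded or unseeded batch cooling crystallization of
    alpha L-glutamic acid (and similar systems) by solving a one-dimensional
    population balance equation with the discrete method (method of classes)
    on a geometric crystal-volume grid, coupled to a lumped solute mass
    balance and a cooling schedule. Nucleation and growth follow power laws
    in relative supersaturation; solubility is a quadratic polynomial in
    temperature. Supports a single well-mixed vessel and a multizonal
    (compartment-network) reduction of a stirred crystallizer, plus
    volume-based crystal size distribution analytics, power-law growth
    kinetics fitting, YAML run configuration, and synthetic fixture
    generation.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
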