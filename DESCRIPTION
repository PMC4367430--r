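Package: ohkin
Title: Hydroxyl Radical Kinetics and Dosimetry for Plasma-Treated Liquids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the generation and loss of hydroxyl radicals (OH) in
    liquids exposed to a nonthermal atmospheric-pressure plasma jet, where
    plasma-initiated UV photolysis sustains OH production below the surface.
    Provides a reaction-network kinetic integrator with photolysis and
    hydroxide-photodetachment source terms, the closed-form second-order
    recombination decay and its lifetime law tau = 2/(alpha*n0), Beer-Lambert
    inversion of UV absorption measurements into absolute densities,
    exponential depth-attenuation fitting, membrane electrostatics, and an
    nT (density times effective exposure time) dose criterion for apoptosis
    of adherent cancer cells. A seeded synthetic-data generator emulates
    decay traces, pulse trains, transmission datasets and pH-dependent
    photodetachment currents with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
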