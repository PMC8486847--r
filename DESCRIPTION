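Package: biofetmc
Title: Modelling and Decoding for Graphene BioFET Molecular-Communication Receivers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis pipeline for a microfluidic molecular
    communication link whose receiver is a DNA-functionalised graphene
    field-effect transistor. Provides microfluidic hydraulics and
    electrolyte-screening constants, electrolyte-gated FET electrostatics
    (series gate capacitance, Debye-screened molecular charge, charge-to-
    current transduction), Langmuir hybridisation kinetics with a closed-form
    Lambert-W finite-pulse response and a numerical ODE cross-check,
    LTI superposition of concentration-encoded on-off-keyed bits,
    moving-mean filtering with difference-based bit detection and BER,
    nonlinear least-squares fitting of all three model layers, and seeded
    synthetic-trace generators so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    pracma,
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
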