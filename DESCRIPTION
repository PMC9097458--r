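Package: plcgkin
Title: Structure-Based Kinetic Modeling of PLC-gamma1 Autoinhibition,
    Activation, and Spatial Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based construction and deterministic simulation of a
    kinetic model of phospholipase C-gamma1 (PLC-gamma1) regulation by its
    SH2 domains.  The molecular state space (nSH2 occupancy, Tyr783
    phosphorylation, cSH2 partner, catalytic-core activity) is expanded
    from a compact set of reaction rules into a mass-action network of
    species and unidirectional reactions, with a shared enhancement factor
    enforcing detailed balance in the receptor-binding/membrane-insertion
    cycle.  Simulation protocols cover receptor dose-response of the
    steady-state active fraction, lifetime (decay) analysis after shutting
    off cytosolic recruitment, scans over hypothetical activating variants,
    and reduction of activation time courses to apparent two-state rate
    constants.  The activation network can also be embedded in a
    one-dimensional reaction-diffusion model of PLC/PKC polarization during
    gradient sensing, with phosphatidic-acid positive feedback, an optional
    PKC-driven feedback loop, and MARCKS regulation of PIP2 availability.
    Networks export to SBML, CSV, and a plain-text rule listing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
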