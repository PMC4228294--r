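Package: csfnet
Title: Starling-Force Network Model of Cerebrospinal Fluid Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lumped-parameter simulator of water and solute exchange between
    the cerebral vasculature, perivascular and extracellular spaces, and the
    cerebrospinal fluid (CSF) compartments.  An eight-compartment,
    twelve-arc network couples Hagen-Poiseuille luminal flow, an amended
    Starling transmembrane flux (proteins, ions and glucose all contribute
    osmotic pressure via van't Hoff), Darcy porous-media flow, active solute
    secretion, and metabolic water production into a stiff nonlinear ODE
    system.  A virtual-experiment layer reproduces ventriculo-cisternal
    perfusion (VCP) with the classical tracer-dilution estimator of nascent
    fluid flow, osmotic dose-response and sensitivity analyses, intravenous
    tracer bolus studies, and chronic intraventricular osmotic loading.
    Unknown conductances, reflection coefficients and secretion rates are
    fitted to published physiological operating points by weighted
    least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
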