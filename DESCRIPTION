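Package: kinhibit
Title: Enzyme Inhibition Kinetics for Slow- and Fast-Binding Inhibitors with Hit-to-Lead Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing enzyme inhibition assays of the cytochrome bc1
    complex and similar targets. Fits slow-binding progress curves for the
    initial rate, steady-state rate and observed first-order rate constant
    (kobs); regresses kobs against inhibitor concentration to obtain apparent
    association and dissociation constants; diagnoses inhibition modality from
    their substrate dependence; and derives microscopic rate constants and the
    inhibition constant Ki. Also fits the Michaelis-Menten inhibition model
    family (competitive, noncompetitive, uncompetitive, mixed) to initial-rate
    grids with AICc model selection and double-reciprocal diagnostics, and
    implements a hit-to-lead triage layer: binding free-energy shifts from Ki
    ratios, ligand efficiency, substitution-candidate enumeration, free-energy
    threshold triage and pesticide-likeness filtering. A seeded synthetic-assay
    generator reproduces the reference experimental designs so the whole
    inference chain is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
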