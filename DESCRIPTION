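Package: cosolvency
Title: Cosolvency Solubility Models and Dissolution Thermodynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of equilibrium mole-fraction solubility of a crystalline
    solute in binary cosolvent + water mixtures across temperature: ideal
    solubility and activity coefficients from fusion calorimetry, Hansen
    solubility parameters of solvent blends, apparent dissolution
    thermodynamics (van't Hoff and Gibbs analysis at the mean harmonic
    temperature) with enthalpy-entropy compensation, and five cosolvency
    correlation models (van't Hoff, Apelblat, Yalkowsky-Roseman,
    Jouyban-Acree, Jouyban-Acree-van't Hoff) validated by percent root mean
    square deviation.  Ships the emtricitabine in PEG-400 + water solubility
    dataset and a seeded generator of van't Hoff-consistent synthetic
    solubility surfaces for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
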