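Package: cosolvr
Title: Co-Solvency Solubility Modeling and Dissolution Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the saturation solubility of a drug in
    binary co-solvent + anti-solvent mixtures as a function of mixture
    composition and temperature. Computes mole-fraction solubility from
    weighed masses, ideal solubility and activity coefficients from fusion
    properties, apparent dissolution thermodynamics by van't Hoff
    regression at the harmonic-mean temperature, enthalpy-entropy
    compensation, and Hansen solubility parameter mixing. Fits and
    compares five co-solvency correlation models (van't Hoff, Apelblat,
    Yalkowsky-Roseman, Jouyban-Acree and Jouyban-Acree-van't Hoff) by
    percentage root-mean-square deviation, ships the published
    baricitinib (DMSO + water) solubility surface as a reference dataset,
    and generates seeded synthetic solubility surfaces for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
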