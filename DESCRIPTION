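Package: eqspec
Title: Metal-Ligand Equilibrium Speciation, Potentiometric Refinement and
    Blood-Plasma Mobilization Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for solution equilibrium studies of metal-ligand systems by
    glass-electrode potentiometry. Provides a damped-Newton mass-balance
    solver for multicomponent equilibria described by overall formation
    constants beta_pqr, simulation of glass-electrode titrations with
    realistic noise, electrode calibration and Gran endpoint diagnostics,
    the classical formation (Z-bar), deprotonation (Q-bar) and protonation
    (n-bar) functions, Levenberg-Marquardt refinement of formation constants
    with parameter standard deviations and Hamilton R-factors, speciation
    distribution diagrams, and a reduced fixed-free-metal blood-plasma model
    for plasma mobilizing index (pmi) curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
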