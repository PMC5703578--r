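Package: mechnet
Title: Logic-Based Differential Equation Modeling of Mechano-Signaling Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construct, simulate, and interrogate logic-based differential
    equation (LDE) models of intracellular signaling networks, with an
    emphasis on cardiomyocyte mechano-signaling. Provides a Netflux-style
    tabular model format (species and reaction sheets, workbook or paired
    CSV), normalized Hill activation functions with continuous AND/OR gate
    algebra, stiff-safe simulation to trajectories and steady states,
    perturbation contexts (input levels, knockdowns, clamps) and
    dose-response curves, qualitative validation against literature
    observation tables with parameter-robustness scans, single and pairwise
    knockdown sensitivity analysis with hub clustering and a
    combination-perturbation synergy screen, plus seeded synthetic network
    generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
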