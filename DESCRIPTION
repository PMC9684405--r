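Package: rascycle
Title: Mass-Action Modeling of RAS Nucleotide Cycling, Covalent KRAS
    G12C Inhibition, and Drug-Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds mass-action reaction networks for competing RAS
    GTPase pools (mutant and wild type) that share a guanine-nucleotide
    exchange factor (GEF), a GTPase-activating protein (GAP, NF1), and a
    downstream effector, with RAS protein turnover. Simulates covalent
    KRAS G12C inhibitor engagement (kinact/Ki kinetics) and EGFR
    inhibition as a reduction of GEF activity, solves for steady-state
    RAS-GTP readouts over two-dimensional dose grids, and scores drug
    combinations with excess-over-Bliss synergy matrices. Includes a
    synthetic-data module that emulates viability dose grids and RAS-GTP
    pulldown experiments for end-to-end pipeline testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
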