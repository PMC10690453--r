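Package: pmcasyn
Title: Alpha-Synuclein Modulation of PMCA and Presynaptic Calcium Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying activation of the plasma
    membrane Ca2+-ATPase (PMCA) by monomeric alpha-synuclein (aSN).
    Fits the Hill equation to Ca2+-titration ATPase activity curves and a
    non-essential-activation model to aSN titrations, solves Ca/Mg/EGTA/ATP
    chelator equilibria for free calcium, simulates presynaptic calcium
    dynamics with a Hodgkin-Huxley membrane model coupled to VGCC influx and
    aSN-modulated PMCA, NCX and leak fluxes, and summarises calcium
    transients (peak height, pre-/post-peak width, moving-average maximum,
    area under the curve). Also provides a tissue-level exon percent-spliced-in
    (PSI) versus gene-expression binning analysis and seeded synthetic-data
    generators for every input so the full pipeline is testable end to end.
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
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
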