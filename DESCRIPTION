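Package: gcdesign
Title: Pareto-Optimal Growth-Coupled Knockout Design for Constraint-Based
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Searches genome-scale constraint-based metabolic models for
    reaction-knockout strategies that couple product synthesis to cell growth.
    A multi-objective genetic algorithm (NSGA-II) maximizes three objectives
    simultaneously: maximum growth rate, guaranteed product flux at maximum
    growth, and a coupling-strength score derived from the production
    envelope. Includes model reduction (dead-reaction removal, lumping of
    unbranched pathways, essentiality screening), redundant-knockout
    minimization, reporting of the Pareto front as CSV and plot, and a
    command-line interface. Models are read from SBML Level 3 (fbc) or a
    COBRA-community-compatible JSON dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    jsonlite,
    xml2,
    optparse,
    methods,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
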