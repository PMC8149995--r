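Package: fluxforge
Title: Genome-Scale Metabolic Network Reconstruction and Flux Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing constraint-based genome-scale metabolic
    models from KEGG-style flat files and simulating them with flux balance
    analysis (FBA). Covers draft assembly of gene-enzyme-reaction networks
    via EC numbers, equation balancing by element and charge conservation,
    chiral standardization, redundancy removal, connectivity-based gap
    filling over weakly connected components, compartmentalization with
    transport/exchange reactions, biomass objective construction from
    measured nutritional composition tables, blocked-precursor diagnosis and
    repair, parsimonious FBA and flux variability analysis for nutrient
    requirement profiling. Includes a synthetic-data generator with planted
    ground truth so the whole pipeline is testable offline, and a built-in
    bounded-variable simplex solver for the linear programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
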