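Package: lacreg
Title: Thermodynamic Models of lac Operon Regulatory Input Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a thermodynamic promoter-occupancy model to two-dimensional
    (cAMP x IPTG) expression landscapes of the Escherichia coli lac operon and
    characterises the resulting regulatory input functions. Provides logic
    phenotyping (AND/OR-type summaries), landscape distance and clustering,
    phylogenetic-signal tests (Pagel's lambda), permutation Mantel tests,
    phylogenetic-diversity representativeness bootstraps, mutual-information
    scans of polymorphic sites against fitted parameters, partial
    least-squares regression of growth lag time on regulatory parameters,
    modified-Gompertz growth-curve fitting with lag extraction, and a
    synthetic-data generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    graphics,
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
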