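Package: oxicap
Title: Antioxidant Capacity Assays, Polymer Degradation Statistics and
    Conceptual-DFT Reactivity Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vitro antioxidant characterization:
    ORAC plate-reader kinetics (area under the fluorescence-decay curve, net
    AUC dose-response slopes and Trolox equivalents), DPPH radical-scavenging
    percentages and IC50 interpolation, FRAP relative reducing power and
    Trolox calibration, hydroxyl-radical-scavenging time courses, polymer
    molar-mass statistics (Mn, Mw, dispersity) for hyaluronic-acid protection
    studies, and Koopmans-type conceptual-DFT reactivity descriptors
    (hardness, softness, electronegativity, electrophilicity, chemical
    potential) together with O-H bond-length analysis, bond dissociation
    enthalpies and ionization potentials from quantum-chemistry summaries.
    Includes mechanistic synthetic-data generators (radical-driven probe
    decay, endpoint dose series, ROS time courses, random chain scission) so
    every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'cdft.R'
    'endpoint-assays.R'
    'hrs.R'
    'io-massdist.R'
    'io-plate.R'
    'io-thermo.R'
    'io-xyz.R'
    'orac.R'
    'oxicap-package.R'
    'pipeline.R'
    'polymer-mass.R'
    'synthetic-data.R'
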