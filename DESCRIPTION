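Package: spiralsort
Title: Label-Free Purification Modelling for Manufactured Red Blood Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico model of a two-stage label-free purification
    process for stem cell-derived red blood cells: synthetic deformability
    cytometry event tables for the heterogeneous end product of in vitro
    erythropoiesis (enucleated cells, nucleated cells, free-floating
    nuclei), a gating classifier on DNA signal and projected area, a
    phenomenological spiral inertial-focusing model of lateral equilibrium
    positions, ROC/AUC based operating flow-rate selection, outlet binning
    with separation efficiency, purity and enrichment metrics, a membrane
    filtration stage, dimensionless channel design calculations (Reynolds,
    Dean, crowding parameter), and threshold-based classification of
    synthetic cytospin images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
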