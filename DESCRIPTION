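Package: ck2qsar
Title: 2D QSAR Modelling of Casein Kinase II Inhibitors from VSA-Binned
    Molecular Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a complete two-dimensional quantitative
    structure-activity relationship (QSAR) workflow for casein kinase II
    (CK2) inhibitors. Molecules are parsed from SMILES or SDF into a
    molecular-graph representation from which ten 2D descriptors are
    computed natively: Gasteiger-Marsili (PEOE) partial-charge binned van
    der Waals surface areas, hydrophobic/polar surface areas,
    Wildman-Crippen SlogP- and SMR-binned surface areas, the Wiener path
    number, and an approximate van der Waals volume. Activity modelling
    uses NIPALS partial least squares regression with leave-one-out
    cross-validation, descriptor selection by contingency statistics and
    relative importance, stratified activity-range train/test splitting,
    and a frozen published linear equation for CK2 pIC50 prediction.
    Synthetic-data generators with known ground truth support end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'params.R'
    'smiles.R'
    'graph.R'
    'peoe.R'
    'vsa.R'
    'crippen.R'
    'descriptors.R'
    'activity.R'
    'pls.R'
    'select.R'
    'equation.R'
    'dataset.R'
    'pipeline.R'
    'synthetic.R'
    'fixtures.R'
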