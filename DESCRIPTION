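Package: pocketgcn
Title: Graph Convolutional Regression of Protein-Ligand Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts protein-ligand binding affinity (pKd/pKi) from the 3D
    structure of the binding pocket with a graph convolutional neural network.
    A pocket is represented as one 13-feature atom matrix plus a set of
    distance-binned binary adjacency matrices; parallel graph-convolution
    blocks (one per distance bin) with symmetric degree normalization and a
    sum-gather readout regress the affinity. Includes the full data pipeline:
    PDB/mol2/SDF reading, pocket extraction at a 4 Angstrom cutoff, Open
    Babel-based atom featurization, PDBbind-style index parsing, train/
    validation splitting, docking-pose augmentation filters, an Adam/MSE
    training harness with early stopping, standard scoring-function metrics
    (RMSE, MAE, Pearson R, regression SD), and a synthetic pocket generator
    with a planted contact-count affinity for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    bio3d,
    ChemmineR,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
SystemRequirements: Open Babel (obabel on the PATH) for atom typing and
    Gasteiger partial charges
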