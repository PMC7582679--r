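Package: tarfish
Title: Consensus In Silico Target Prediction for Compound Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A consensus "target fishing" pipeline for natural-product
    compound classes. Loads and standardizes a compound library (salt
    stripping, charge neutralization, enumeration of unspecified
    stereocenters), computes circular and path fingerprints, and predicts
    protein targets with a similarity-ensemble engine (thresholded Tanimoto
    raw scores calibrated against random ligand ensembles, z-scores and
    extreme-value E-values) plus a hybrid 2D/3D channel combining path
    fingerprints with electroshape descriptors through logistic regression.
    External prediction matrices (for example from a pharmacophore model
    database) are ingested and binarized, known bioactivities are mined from
    a pluggable backend and subtracted, and a consensus score is assigned to
    every remaining compound-target pair. Targets are ranked and selected by
    frequency, pathway consistency, novelty and assay availability, and
    percent-inhibition assay readouts are classified into activity calls.
    Includes a seeded synthetic-fixture generator with planted ground truth
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
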