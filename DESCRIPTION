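Package: exmrecon
Title: Simulation and Reconstruction of Expansion-Microscopy Neural Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-simulates 20x expansion-microscopy confocal image stacks of
    densely membrane-labeled neural tissue from known ground-truth label volumes
    (Debye-integral confocal point-spread function, stochastic fluorophore
    labeling, puncta clustering, Poisson and read noise), and reconstructs neuron
    morphology from such stacks with a trainable 3D convolutional boundary
    detector, H-minima watershed over-segmentation, learned hierarchical
    supervoxel agglomeration, and barcode-consistency merging guided by
    error-free cell-identity RNA barcodes. Reconstructions are scored with
    foreground-restricted Rand and information-theoretic split, merge and
    F-scores.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    randomForest,
    jsonlite,
    yaml,
    tiff,
    withr,
    rlang
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
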