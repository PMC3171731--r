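Package: vorsite
Title: Protein Binding-Site Prediction from Voronoi Residue Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein binding-site residues on a protein
    surface by scoring exposed residues with a two-step random forest.
    Per-residue structural, energetic, evolutionary and crystallographic
    B-factor features are combined with descriptors of each residue's
    structural environment defined by a three-dimensional Voronoi
    tessellation of the heavy atoms (with Euclidean-sphere, sequence-window
    and no-environment alternatives). The second classification step feeds
    the first-step scores of neighbouring residues back as additional
    features, smoothing predictions over contiguous surface patches.
    Includes a synthetic two-chain complex generator with planted interface
    signal for end-to-end testing, evaluation utilities (recall, precision,
    Matthews correlation, accuracy, F1, ROC/AUC, paired-bootstrap AUC
    comparison) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    graphics,
    jsonlite,
    optparse,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
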