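Package: rptraj
Title: Random Nonlinear Compression and Kinetic Analysis of Molecular
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compresses high-dimensional molecular-dynamics feature spaces
    with untrained random feed-forward networks (ELU activations, Xavier
    weight initialization, min-max standardized outputs) or linear random
    maps, and evaluates how well the compressed features retain slow
    conformational dynamics. Includes featurization from PDB topologies
    (pair distances, exponential contacts, backbone dihedrals, aligned
    positions), time-lagged independent component analysis (TICA) with PCA
    baselines, Markov state model estimation with implied timescales versus
    lag time, fraction-of-native-contact cluster summaries, multi-trial
    aggregation, and a synthetic metastable-dynamics generator with
    analytically known relaxation timescales for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
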