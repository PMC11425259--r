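Package: esiptscreen
Title: Multi-Level Machine Learning Screening for ESIPT Fluorophores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual-screening toolkit for excited-state intramolecular
    proton transfer (ESIPT) fluorophore discovery. Provides molecule I/O and
    similarity-based library curation, MACCS/ECFP4 fingerprints and a 2D
    descriptor panel with variance/correlation pruning, a two-stage
    classification cascade (ESIPT vs conventional molecules, ESIPT vs other
    fluorophores) plus an energy-barrier regressor evaluated with fold-rate
    criteria, ECOD outlier exclusion, recursive feature elimination, exact
    Shapley attribution for tree ensembles with fingerprint-bit to
    substructure mapping, three configurable candidate-scoring strategies
    (safety, pharmacokinetics, structural innovation), and a synthetic
    molecule generator with planted proton donor-acceptor motifs for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    e1071,
    rpart,
    nnet,
    xgboost,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
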