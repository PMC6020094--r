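Package: admetkit
Title: QSAR Model Building and ADMET Profiling Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for building quantitative
    structure-activity relationship (QSAR) models of ADMET (absorption,
    distribution, metabolism, excretion, toxicity) endpoints from
    small-molecule structures. Covers molecule reading and washing (salt
    disconnection, largest-fragment retention), molecular descriptors and
    fingerprints (path-based, MACCS keys, extended-connectivity),
    diversity-based train/test splitting, three-rule descriptor pre-filtering
    and random-forest recursive feature elimination, two-stage grid-searched
    model training with imbalance-aware strategies (balanced per-tree
    sampling and resampling consensus ensembles), a regression and
    classification metric suite including fold-error rates and Cohen's kappa,
    drug-likeness rule screening, per-molecule ADMET profiling, and
    accurate/range/similarity search over a local ADMET record store.
    Synthetic molecule corpora and feature/label generators with known ground
    truth make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    ChemmineR,
    igraph,
    randomForest,
    ranger,
    e1071,
    rpart,
    mixOmics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
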