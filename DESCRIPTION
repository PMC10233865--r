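Package: hetlink
Title: Link Prediction and Target Expansion on Layered Chemical-Target Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds layered heterogeneous networks of chemicals and protein
    targets from chemical-target activity records, fingerprint-based
    chemical-chemical similarity (Tanimoto-thresholded) and
    confidence-thresholded protein-protein interactions; benchmarks five
    link-prediction algorithms (node2vec with a skip-gram embedding and a
    logistic edge classifier, Adamic-Adar, Jaccard, preferential attachment,
    and spectral Laplacian embedding) under repeated 6:3:1 resampling with
    AUROC and average-precision metrics; and extracts newly predicted
    herbal-chemical to drug-target edges with expansion accounting. A
    planted-block synthetic-network generator makes every stage runnable and
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
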