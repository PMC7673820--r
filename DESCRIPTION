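Package: cellConsensus
Title: Ensemble Consensus Clustering of Single Cells via Graph-Regularized
    Bernoulli Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fuses the label outputs of several single-cell clustering
    methods into a weighted consensus co-membership matrix (with
    Calinski-Harabasz pre-learning weights), then factorizes the binarized
    consensus with a symmetric Bernoulli factor model carrying
    automatic-relevance-determination priors and a k-nearest-neighbour
    graph Laplacian penalty on the expression feature space. Damped
    multiplicative updates with multi-restart fitting yield hard cluster
    assignments and an automatically determined cluster count. Includes
    CPM normalization, partition I/O, adjusted Rand index and normalized
    mutual information, a synthetic ensemble generator for benchmarking,
    and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
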