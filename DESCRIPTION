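Package: donkey
Title: Density-Based Clustering by Adaptive Kernel Density Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clustering of small, heterogeneous multidimensional data sets by
    direct estimation of the underlying probability density. A Gaussian kernel
    density estimate with a full covariance matrix is fitted by maximising the
    leave-one-out likelihood, locally rescaled with Abramson variable
    bandwidths, and its local maxima are taken as cluster centres. Points are
    assigned by safeguarded Newton ascent, and maxima separated only by
    high-lying first-order saddle points are merged via an eigenvector-following
    saddle search. Includes entropy-based evaluation metrics (homogeneity,
    completeness, V-measure), seeded synthetic benchmark generators, and a
    frame-by-frame pipeline for clustering molecular-dynamics trajectory
    ensembles into reaction channels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
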