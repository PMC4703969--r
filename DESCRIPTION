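Package: camix
Title: Convex Analysis of Mixtures for Unsupervised Expression Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully unsupervised deconvolution of heterogeneous bulk
    gene-expression samples by convex geometry. Sum-standardized gene
    vectors form a scatter simplex whose vertices host subpopulation
    specific marker genes; camix aggregates gene vectors by affinity
    propagation, locates the simplex vertices by exhaustive combinatorial
    search under a margin-of-error criterion, selects the number of
    subpopulations by minimum description length, and estimates mixing
    proportions and subpopulation-specific expression profiles by
    standardized marker averaging and non-negative least squares. Includes
    a ground-truthed synthetic mixture generator and evaluation criteria
    (cross-talk E1 index, marker confusion, perturbation baselines).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
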