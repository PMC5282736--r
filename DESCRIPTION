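Package: lobomorph
Title: Morphospace Disparity Analysis of Discrete Morphological Character Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying morphological disparity from discrete
    (cladistic) character matrices, built around the workflow used to compare
    lobopodian clades in morphospace: reading and validating NEXUS/CSV
    character matrices with missing, inapplicable and polymorphic cells;
    Gower, MORD and Hamming dissimilarities under pairwise deletion;
    principal coordinates analysis with Broken-Stick axis selection;
    jackknifed sums of ranges and variances with permutation tests;
    kernel-density hypervolumes with Sorensen-Dice overlap, point-inclusion
    tests and centroid distances; neighbour-joining phenograms and k-means
    cluster-number assessment; and a synthetic-data generator with known
    group structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
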