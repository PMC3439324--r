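Package: reclink
Title: Multi-Source Record Linkage by Threshold Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates person records from multiple datasets that lack a
    shared identifier. Implements typo- and phonetics-aware attribute
    distances (edit, reversal, nickname, truncation, name, and Metaphone
    phonetic distance), a threshold-bounded banded edit distance with
    cross-attribute budget propagation, and four single-linkage clustering
    strategies: full dendrogram construction with a threshold cut, partial
    dendrogram construction, structure-free cluster growth, and a two-phase
    algorithm with l-mer blocking on the last name. Includes cluster-level
    evaluation metrics (accuracy, completeness, four-category analysis) and
    a seeded generator of synthetic corrupted person records with ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
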