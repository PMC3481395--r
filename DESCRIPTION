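Package: sfams
Title: Iterative Protein Family Clustering by Sifting and Markov Clustering
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo clustering of protein sequences into globally homologous
    families ("sifting families"): all-vs-all local alignment with a dual
    e-value/coverage homology filter, Markov clustering of the resulting
    percent-identity graph, per-family profile models with empirical e-value
    calibration, and an iterative database-update loop that sifts new
    sequences against existing family profiles before re-clustering the
    residue. Includes family-quality metrics (precision, recall,
    leave-one-out recall), a consensus-sequence family network with clan
    construction, fragment classification of unclustered sequences,
    majority-rules functional annotation with Fisher-exact enrichment scans,
    and a seeded synthetic-corpus generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
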