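Package: qstree
Title: Quartet-Score Species Tree Inference Under the Multispecies Coalescent
Version: 0.1.0
Authors@R:
    person("qstree", "developers", email = "qstree@example.org", role = c("aut", "cre"))
Description: Estimates an unrooted species tree from a collection of
    single-copy gene trees by maximizing the (optionally weighted) quartet
    support score, the number of four-species subtrees on which the species
    tree and the gene trees agree. Provides an exact scoring engine that
    aggregates per-tripartition anchored quartet counts without enumerating
    quartets, a search combining greedy stepwise taxon placement,
    nearest-neighbor-interchange hill climbing, and a constrained dynamic
    program over tripartitions, branch annotation with quartet support,
    coalescent-unit lengths and local posterior probabilities, and a
    multispecies-coalescent gene tree simulator so that every statistical
    property is testable from synthetic data. Handles polytomies, missing
    taxa, multiple individuals per species, and support- or length-based
    quartet weighting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
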