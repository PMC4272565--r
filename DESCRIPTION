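Package: pipeppi
Title: Sequence-Based Protein-Protein Interaction Prediction by Window
    Co-Occurrence (PIPE)
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts physical protein-protein interactions from primary
    sequence alone using the PIPE (Protein Interaction Prediction Engine)
    window co-occurrence method: overlapping sequence windows are compared
    with the PAM120 substitution matrix against a database of known
    interactions, a co-occurrence landscape is accumulated per query pair,
    and a modified median filter yields a score in [0,1]. Includes a
    desk-scale scheduler/worker scan driver, leave-one-out evaluation with
    class-prevalence adjustment and operating-point selection, network
    topology and annotation-agreement analyses (hubs, betweenness
    centrality, shared-annotation and reachability statistics), a
    paraclique complex decomposition (Bron-Kerbosch maximal cliques with
    merge and glom stages and hypergeometric term enrichment), and seeded
    synthetic-data generators (motif-planted interaction databases and
    planted-partition graphs) so the full pipeline can be exercised
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
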