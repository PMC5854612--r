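Package: modeval
Title: Evaluation Framework for Gene Expression Module Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking gene module detection methods against
    regulatory-network-derived gold standards. Derives known module sets from
    a regulatory network under three module definitions (minimal and strict
    co-regulation, Markov-cluster interconnected subgraphs), scores observed
    module sets with overlap-aware metrics (CICE-BCubed precision and recall,
    recovery and relevance), normalizes scores against permutation null
    models, scores regulator-target coverage by Fisher enrichment and the
    aucodds area statistic, computes internal cluster validity and
    co-expression quality measures, and runs grid-search parameter tuning
    with cross-dataset transfer. A built-in generator plants co-regulated
    modules with global or local co-expression so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    cluster,
    igraph,
    optparse
Config/testthat/edition: 3
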