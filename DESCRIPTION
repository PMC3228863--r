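Package: irefkit
Title: Consolidation, Search and Mining of Protein Interaction Records
Version: 0.1.0
Authors@R: person("iRefKit", "Developers", role = c("aut", "cre"),
    email = "irefkit@example.org")
Description: Headless toolkit for working with consolidated protein-protein
    interaction data. Computes sequence-hash identifiers (ROGID for
    interactors, RIGID for interactions) that group redundant records from
    multiple source databases, reads and writes an iRefIndex-style PSI-MITAB
    2.5 dialect including bipartite serialization of n-ary (complex) records,
    assigns canonical representatives to splice-isoform groups, materializes
    search results as an attribute-rich multigraph with pseudonodes for n-ary
    data, and provides mining tools: detection of spoke-represented
    complexes, disease-group search, and a group-versus-group adjacency
    matrix classifier. Includes a seeded synthetic corpus generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    openssl,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
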