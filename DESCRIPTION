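Package: ancsyn
Title: Phylogeny-Aware, Scale-Free Reconstruction of Ancestral Synteny
Version: 0.1.0
Authors@R: person("ancsyn", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers which groups of orthologous genes (OGs) were syntenic in a
    chosen ancestral node of a species cladogram, without requiring
    collinearity or hard limits on syntenic block size. Per-species matrices
    of minimum intervening-gene distances between OG pairs (including paralog
    self-pairs) are polarized over the tree; ancestral pair distances are
    estimated as the mean over supporting clades of the major mode of a
    kernel density estimate. An OG network trimmed at a depth-dependent
    distance threshold is decomposed into maximal cliques of the raw graph,
    and the extant descendants of each ancestral block are recovered in every
    genome and classified as micro-syntenic, macro-syntenic or non-syntenic.
    Includes a synthetic multi-species genome simulator with ground truth for
    end-to-end validation, and a staged, resumable command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
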