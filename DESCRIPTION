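Package: miconet
Title: Microbial Co-Occurrence Networks, Keystone Taxa and Network Robustness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for genus-level 16S amplicon count tables:
    prevalence-based contaminant flagging against negative controls,
    low-abundance taxon filtering, centered log-ratio transformation and
    Dirichlet Monte-Carlo Kruskal-Wallis differential abundance, alpha and
    Jaccard beta diversity with PERMANOVA, SparCC compositional correlation
    inference, thresholded signed co-occurrence networks with topology
    summaries and keystone-taxon identification, and network-robustness
    simulation by targeted node removal (random, degree, betweenness,
    cascading) and random node addition. Includes a synthetic-data
    generator with planted, modular basis-correlation structure so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    biomformat,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
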