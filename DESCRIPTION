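Package: citegene
Title: Gene Co-Occurrence and Gene-Citation-Gene Networks from Citation Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds explicit (within-article co-occurrence) and implicit
    (citation-mediated) gene networks from an entity-annotated citation
    corpus, ranks genes and gene pairs by network centrality measures
    (degree, weighted degree, closeness, betweenness, PageRank), detects
    communities by modularity, labels genes and clusters with dominant
    disease categories, and benchmarks candidate pairs against a gene
    interaction reference. Includes a synthetic corpus generator with
    planted interacting pairs for end-to-end validation, and transcribed
    literature fixtures with recomputation of their printed aggregates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
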