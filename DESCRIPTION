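Package: pathwaynet
Title: Pathway-Level Functional Networks from Gene Ontology Semantic Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds high-level functional networks in which nodes are curated,
    non-redundant pathway gene sets and edges are Gene Ontology semantic
    similarities between the pathways' minimal enriched-term profiles.
    Provides readers for OBO ontologies, GAF gene annotations and GMT gene
    sets; pathway curation (deduplication, disease-name filtering, annotation
    coverage); Fisher's exact over-representation analysis with
    Benjamini-Hochberg correction; greedy set-cover reductions of enriched-term
    profiles and of pathway redundancy; Wang and Resnik term similarity with
    pairwise-average and best-match-average set aggregation; edge pruning by a
    node/edge-retention threshold scan with network statistics and
    degree-preserving randomization; disease-module mapping with shortest-path
    permutation tests; and a deterministic synthetic-data generator emulating
    the statistical shape of pathway, ontology and disease-annotation
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
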