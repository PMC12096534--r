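Package: coocrdf
Title: Reified RDF Co-Occurrence Graphs from Biomedical Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds knowledge graphs of chemical-gene-disease co-occurrence
    associations mined from biomedical literature. Starting from a
    document-entity mention table, the package computes asymmetric
    TF-IDF-style co-occurrence scores, truncates prioritized neighbor
    lists, mints standard-conformant IRIs for compounds (CIDs), diseases
    (DZIDs) and lowercased gene symbols, serializes the reified
    co-occurrence model to Turtle and N-Triples partitioned by subdomain,
    validates the output against SHACL shapes, and answers literature-mining
    questions (top co-mentioned neighbors, co-mentioning references,
    implicit disease links via genes, multi-gene chemical hits, comorbidity
    gene candidates) against the RDF store. A seeded synthetic-corpus
    generator with Zipf-skewed mention frequencies and planted associations
    makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
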