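# coocrdf

Build, validate, and query RDF knowledge graphs of named-entity
co-occurrences in biomedical literature.

Text mining of titles and abstracts yields, for each reference, the set
of chemicals (compounds), genes/proteins, and diseases it mentions.
`coocrdf` turns such a document–mention table into a semantic graph in
which every retained chemical–gene–disease association is a first-class,
reified RDF node carrying a score — the representation behind
literature "knowledge panels" that list, e.g., the diseases most
strongly co-mentioned with a drug. The package is aimed at
cheminformatics and drug-discovery groups who want co-mention evidence
as linked data they can join with other RDF resources.

## The model in brief

For a corpus of *N* references, with *c(A,B)* the number of references
mentioning both entities and df(*B*) the number mentioning *B* at all,
the directed association *A → B* is scored

> S_raw(A → B) = c(A,B) · log₁₀(N / df(B)),  S_CO = round(100 · S_raw)

a TF-IDF-variant statistic: co-mentions with ubiquitous entities are
discounted. Scores are asymmetric (only the object's document frequency
enters), and each entity keeps only its top-1000 neighbors of each kind,
so neighborhood membership itself is directional. Every retained pair
becomes a co-occurrence node with five triples:

```turtle
cooccurrence:CID3715_DZID8173
    rdf:type       sio:SIO_000993 ;              # chemical-disease association
    rdf:type       vocab:TextMinedCooccurrence ; # provenance marker
    rdf:subject    compound:CID3715 ;
    rdf:object     disease:DZID8173 ;
    sio:SIO_000300 "59500"^^xsd:integer .        # "has value"
```

Compound/disease IRIs use numeric `CID`/`DZID` identifiers; gene IRIs
are lowercased gene symbols, percent-encoded except for letters, digits
and `/ - _ : .`. Output is partitioned by subject type into subdomain
directories (`cooccurrence`, `reference`, `compound`, `gene`,
`disease`, `journal`, `author`, `grant`, `organization`) as Turtle or
N-Triples, ships with SHACL shapes describing the contract, and is
queryable in-package or through the bundled SPARQL 1.1 templates
(`inst/sparql/`).

## Worked example

```r
library(coocrdf)

cfg <- synthetic_config(
  n_refs = 300, seed = 42,
  planted_pairs = list(list(a = "compound:10", b = "disease:6",
                            enrichment = 5)))
corpus <- generate_corpus(cfg)
bundle <- build_bundle(corpus$records, corpus$annotations)
bundle
#> <graph_bundle>
#>   cooccurrence   28290 triple(s)
#>   reference       4584 triple(s)
#>   compound         200 triple(s)
#>   gene             702 triple(s)
#>   disease          100 triple(s)
#>   journal           40 triple(s)
#>   author           195 triple(s)
#>   grant            304 triple(s)
#>   organization       6 triple(s)

validate_bundle(bundle, emit_shapes())
#> <validation_report: conforms>

store <- load_store(bundle)
top_neighbors(store, "compound:10", "disease", limit = 5)
#> # A tibble: 5 × 3
#>   neighbor   serialized_score label
#>   <chr>                 <int> <chr>
#> 1 disease:6               623 Disease 006
#> 2 disease:3               412 Disease 003
#> 3 disease:1               403 Disease 001
#> 4 disease:12              340 Disease 012
#> 5 disease:65              248 Disease 065
```

The corpus planted a fivefold-enriched association between
`compound:10` and `disease:6`; the query recovers it as the compound's
top disease neighbor, with the serialized score (623 = 100 × the raw
TF-IDF-style score, rounded) and the SKOS preferred label joined from
the disease subdomain. `corefs(store, "compound:10", "disease:6")`
then lists the co-mentioning references, most recent first, with
journal, title, and PMC availability — the drill-down used to read a
surfaced association in context.

The same stages are scriptable from a shell:

```sh
Rscript inst/cli/cooccur.R generate  --output corpus/ --n_refs 2000 --seed 1
Rscript inst/cli/cooccur.R serialize --input corpus/ --output rdf/ --format ntriples
Rscript inst/cli/cooccur.R validate  --input rdf/            # exit 1 on violation
Rscript inst/cli/cooccur.R query     --input rdf/ --usecase usecase1 \
        --anchor compound:10 --kind disease
```

## Input format

A corpus directory holds `refs.tsv` (UTF-8, tab-separated, one
reference per line): `ref_id`, ISO date, journal, ISSN, title,
`is_review` (0/1), `pmc_id` (may be empty), `authors` (`;`-joined),
`grants` (`;`-joined `number|agency`, number may be empty for grantless
acknowledgments), MeSH headings (`;`-joined), and mentions (`;`-joined
`kind:id` tokens, `kind` ∈ compound/gene/disease). Optional sibling
tables supply annotations: `disease_labels.tsv` (dzid, label),
`gene_records.tsv` (gid, symbol, taxon, name), `compound_roles.tsv`
(cid, role), `compound_labels.tsv` (cid, label). A YAML dialect
(`refs.yaml`) is available via `format = "structured-text"`.

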