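---
title: "Modeling literature co-occurrence associations as RDF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling literature co-occurrence associations as RDF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coocrdf)
```

## The problem

Text mining of biomedical titles and abstracts produces, for every
literature reference, the set of chemical (compound), gene/protein, and
disease entities it mentions. Two entities mentioned in the same
reference are *co-occurrence neighbors*; aggregated over millions of
references, co-mention statistics expose chemical–gene–disease
relationships — drug side effects, comorbidity genes, implicit
drug–disease links — without requiring curated assertions. `coocrdf`
implements the full path from a document–mention table to a queryable
knowledge graph:

1. score every directed entity pair with a TF-IDF-style co-occurrence
   statistic,
2. keep a prioritized, truncated neighbor list per entity and neighbor
   kind,
3. mint stable IRIs and serialize the associations as reified RDF nodes,
   partitioned by subdomain,
4. validate the output against SHACL shapes, and
5. answer five classes of literature-mining questions against the graph.

Genes and proteins are deliberately conflated into a single gene
namespace keyed by the lowercased gene symbol: the literature uses
protein and gene names interchangeably, and mined mentions usually lack
organism information. Species resolution is layered on separately
through numbered gene records (`GID` nodes carrying an organism taxon
and a "has gene symbol" link).

## The co-occurrence score

For a corpus of $N$ references, let $c(A,B)$ be the number of
references mentioning both $A$ and $B$, and $\mathrm{df}(B)$ the number
mentioning $B$ at all. The directed score of the association
$A \rightarrow B$ is

$$ S_{\mathrm{raw}}(A \rightarrow B) \;=\; c(A,B)\,
   \log_{10}\!\frac{N}{\mathrm{df}(B)} , $$

a document-frequency-weighted co-mention count from the TF-IDF family:
co-mentions with ubiquitous entities (high $\mathrm{df}$) are
discounted, co-mentions with specific entities are amplified. Because
only the *object's* document frequency enters,
$S(A\rightarrow B) \neq S(B \rightarrow A)$ in general. The exact
closed form used by the production resource is not published alongside
the model; this default reproduces every structural property the model
depends on (asymmetry, non-negativity, monotonicity in $c$, antitonicity
in $\mathrm{df}$) and is pluggable — `scoring_params(score_fun = ...)`
accepts any replacement with the same signature.

Scores are serialized as integers, $S_{CO} = \mathrm{round}(100 \cdot
S_{\mathrm{raw}})$, rounding half away from zero (the convention is only
"nearest integer"; the half-tie direction is this package's choice and
is asserted by an independent recomputation in the tests).

### Neighbor lists, truncation, and ordering

For each entity and each neighbor kind the scored neighbors are sorted
and truncated to the top `K = 1000`. Truncation is the second source of
asymmetry: a disease can sit in a rare chemical's short list while the
chemical is pushed out of the disease's crowded list.

Two ordering rules coexist and are worth stating precisely:

* **List construction** sorts by raw score descending, ties broken by
  object IRI ascending — the raw score is the finest-grained key
  available pre-serialization, and the IRI tie-break makes truncation
  deterministic.
* **Store-level queries** can only see the serialized integer, so all
  query operations (and their test oracles) order by serialized score
  descending, then object IRI ascending. The two orders can disagree
  only for pairs whose raw scores differ by less than half a
  serialization unit ($5 \times 10^{-3}$), which is also why the
  equality between `top_neighbors()` and the constructed list is
  asserted on the (neighbor, score) set rather than on sub-rounding
  order.

## The RDF model

Every retained directed pair becomes a *reified co-occurrence node*
carrying exactly five triples under the default profile:

```
cooccurrence:CID3715_DZID8173
    rdf:type      sio:SIO_000993 ;            # chemical-disease association
    rdf:type      vocab:TextMinedCooccurrence ;
    rdf:subject   compound:CID3715 ;
    rdf:object    disease:DZID8173 ;
    sio:SIO_000300 "59500"^^xsd:integer .     # "has value"
```

The association classes for the three mixed pair kinds are the SIO
terms (SIO_000993, SIO_001257, SIO_000983). The same-kind classes
(compound–compound, gene–gene, disease–disease) have no published SIO
term and default to vocabulary-namespace classes; both they and the
text-mining provenance marker are overrideable through
`predicate_profile()`. The score attaches directly to the co-occurrence
node — the query idiom pairs the association class with "has value", so
no intermediate value node is modeled.

References link to their mentioned entities with
`vocab:discussesAsDerivedByTextMining` and to their metadata with DCMI
terms (title, date), PRISM (journal name, ISSN), and FRAPO (grants,
funding agencies). The exact bibliographic property local names are not
fixed by the model's figures, so they are profile-exposed with
reasonable defaults. A funding acknowledgment without a grant number is
modeled as a *direct* reference-to-agency triple, with no grant node —
mirroring articles that thank an agency without citing a grant.

Year-only publication dates are completed to January 1 of that year at
construction so that recency sorting is total; date ties in reference
queries break by reference id descending.

### IRIs

Compounds and diseases use their numeric identifiers (`CID3715`,
`DZID8173`). Gene IRIs are the lowercased symbol with selective
percent-encoding: letters, digits and the five exception characters
`/ - _ : .` pass through; every other character is encoded as its
UTF-8 octets with uppercase hex (`%20` space, `%40` `@`, `%28`/`%29`
parentheses). Co-occurrence node IRIs concatenate the two entity tokens
with `_`; since `_` also passes through unencoded in symbols, parsing
tokenizes at the first `_` whose two sides are both valid entity
tokens. A symbol such as `a_b` therefore round-trips as an entity IRI
but is ambiguous inside a co-occurrence local name — an accepted,
documented limitation shared with any separator-based scheme.

### Partitioning and formats

Triples are grouped by the namespace of their subject into subdomains
(`cooccurrence`, `reference`, `compound`, `gene`, `disease`, `journal`,
`author`, `grant`, `organization`), each written to its own
subdirectory as Turtle or N-Triples. Files are canonically sorted, so
identical inputs produce byte-identical trees. The writers avoid blank
nodes entirely (RDF collections in the shapes graph are skolemized),
which keeps both formats line-oriented and the write→parse round trip
exact; emitted files are additionally cross-checked against an
independent third-party parser in the test suite.

## SHACL validation

`emit_shapes()` encodes the model contract: co-occurrence nodes
(targeted as subjects of `rdf:subject` *or* `rdf:object`, so that a
dropped link cannot also remove the node from the target set) need
exactly one subject, one object, one non-negative integer score, and at
least one type among the configured association classes; reference
nodes carry at most one title and date; and every entity IRI reachable
from a reification link or a mention must match the entity grammar —
`CID`/`DZID` digits or a gene local name free of bare uppercase letters
(percent-escape hex octets are allowed, since the encoder emits
uppercase hex). `validate_bundle()` interprets exactly the SHACL
vocabulary the shapes use (`minCount`, `maxCount`, `datatype`,
`nodeKind`, `minInclusive`, `pattern`, `qualifiedValueShape` + `in`,
and the three target kinds); shapes beyond that subset are out of
scope. Sensitivity is demonstrated with a six-operator defect catalog
(`mutate_bundle()`), each member of which must produce a
non-conformance naming the defective node.

## Querying

All five use-case operations run as triple-pattern joins over the
loaded store — the RDF graph is the only data they see; the pre-RDF
record scans exist solely as independent test oracles. The equivalent
SPARQL 1.1 texts ship under `inst/sparql/` (via `use_case_query()`) for
use with external engines, and the test suite executes two of them with
an independent SPARQL engine to pin the templates to the model.

| operation | question |
|---|---|
| `top_neighbors()` | top-25 neighbors of one kind for an anchor |
| `corefs()` | most recent references co-mentioning a pair, with review/PMC filters |
| `implicit_diseases()` | diseases reached via the anchor chemical's top gene, flagged by direct co-mention |
| `chemicals_for_genes()` | role-filtered compounds in every gene's neighbor list, by score sum |
| `count_refs_mentioning_all()` | references mentioning a compound and all genes at once |
| `genes_for_diseases()` | human genes shared by two diseases' neighbor lists |

Unknown anchors return empty results rather than errors, matching
SPARQL's open-world semantics. When several genes tie for a chemical's
top gene, the deterministic ordering (score, then IRI) picks the first.
With `human_only = TRUE`, a symbol without a human gene record drops
out of the comorbidity result entirely (the name join is mandatory, as
in the corresponding SPARQL pattern).

## The synthetic corpus generator

Because realistic mention data cannot ship with the package, the
generator produces corpora with the statistical structure the pipeline
assumes; its defaults are fixed study conditions, not tuning knobs:

* **Pools and skew** — 150 compounds, 120 genes, 100 diseases with
  Zipf-distributed mention frequencies, exponent 1.1 (word- and
  entity-frequency distributions in large text corpora are classically
  Zipfian with exponents near 1).
* **Mentions per reference** — shifted Poisson with mean 6, minimum 1:
  a title plus abstract mentions a handful of entities.
* **Metadata** — dates uniform over 2010–2024, 20 journals, 200
  authors, 6 funding agencies; 15% reviews, 30% PMC availability, 20%
  grantless agency acknowledgments.
* **Planted pairs** — a planted association forces both entities into a
  reference with probability $q$, solved (quadratically) so that the
  *realized* joint-to-independence ratio equals the requested
  enrichment; the naive $q=(E-1)p_Ap_B$ under-delivers because forcing
  the pair inflates both marginals. For very common entities the
  achievable ratio saturates below the request and the generator
  refuses rather than silently under-planting. Tests plant
  mid-frequency entities (compound rank 10, disease rank 6), chosen
  from this feasibility analysis so the expected co-mention count at
  $n = 2000$ is ≈ 45 — large enough that the realized ratio
  concentrates well inside its acceptance band.
* **Planted quadruples** — inserted into exactly the requested
  references; accidental extra full-quadruple co-mentions are broken by
  removing the compound.

What the generator does *not* emulate: mention-level NER noise
(synonymy, false positives), correlated topics across references,
realistic MeSH vocabularies, or bursty author/journal structure.
Passing tests therefore demonstrate the correctness of the scoring,
serialization, validation and query machinery under the stated
statistical assumptions — not the biological quality of scores on real
mined data, which depends on the upstream entity recognizer.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on corpora of 40–2000
references (oracle-equivalence sweeps use 20 seeds at 150 references;
planted-recovery sweeps 20 seeds at 800), sizes at which brute-force
oracles are exact and fast while every code path — truncation,
asymmetry, planting — is still exercised. Degenerate inputs are defined
errors: an empty corpus, inconsistent counts ($c > \mathrm{df}(B)$ or
$\mathrm{df}(B) > N$), a non-positive CID/DZID, an empty gene symbol,
infeasible planting. Scores of zero ($\mathrm{df}(B) = N$) are kept:
the record exists, with serialized value 0.

## A worked example

```{r example}
cfg <- synthetic_config(
  n_refs = 300, seed = 42,
  planted_pairs = list(list(a = "compound:10", b = "disease:6",
                            enrichment = 5)))
corpus <- generate_corpus(cfg)
bundle <- build_bundle(corpus$records, corpus$annotations)
bundle

validate_bundle(bundle, emit_shapes())

store <- load_store(bundle)
top_neighbors(store, "compound:10", "disease", limit = 5)
```

The planted disease surfaces at the top of the anchor compound's
neighbor list with its serialized score and preferred label — the same
retrieval the literature knowledge panel performs.

```{r corefs}
corefs(store, "compound:10", "disease:6", limit = 3)
```

## Limitations

* The scoring default stands in for an unpublished closed form; swap in
  the exact formula via `score_fun` when available.
* The SHACL engine interprets the emitted constraint subset, not the
  full SHACL recommendation; the shapes file remains standard Turtle
  consumable by complete validators.
* ShEx emission, cross-resource `skos:closeMatch` interoperability
  links, and protein `encodedBy` extensions are out of scope.
* Tie-breaking below the serialization resolution is deterministic but
  package-defined; a store populated by other tooling may order
  equal-score neighbors differently.
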