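#' Predicate and class profile of the graph model
#'
#' All vocabulary choices of the serialized model in one place. Defaults
#' follow the PubChemRDF co-occurrence conventions wherever an external
#' ontology names the term: SIO_000993 / SIO_001257 / SIO_000983 for the
#' chemical-disease, chemical-gene and gene-disease association classes,
#' SIO_000300 ("has value") for the serialized score,
#' `vocab:discussesAsDerivedByTextMining` for mentions, SKOS prefLabel for
#' labels, BAO_0002870 ("has gene symbol") and `up:organism` for
#' species-specific gene records, and RO_0000087 ("has role") with
#' `vocab:FDAApprovedDrugs` for compound roles. Same-kind association
#' classes, the text-mining provenance marker, the review-article class,
#' the PMC predicate and the exact bibliographic property locals
#' (DCMI/PRISM/FRAPO namespaces) are model choices of this package and
#' remain config-exposed.
#'
#' @param ns a [namespace_table()].
#' @param ... named overrides of any profile field (values may be CURIEs,
#'   expanded against `ns`, or absolute IRIs). `association_classes` must
#'   be a full named vector over the six pair classes.
#' @return an object of class `predicate_profile`.
#' @export
predicate_profile <- function(ns = namespace_table(), ...) {
  x <- function(curie) ns_expand(curie, ns)
  profile <- list(
    association_classes = c(
      "compound-compound" = x("vocab:CompoundCompoundCooccurrence"),
      "compound-gene"     = x("sio:SIO_001257"),
      "compound-disease"  = x("sio:SIO_000993"),
      "gene-gene"         = x("vocab:GeneGeneCooccurrence"),
      "gene-disease"      = x("sio:SIO_000983"),
      "disease-disease"   = x("vocab:DiseaseDiseaseCooccurrence")),
    score_predicate     = x("sio:SIO_000300"),
    mention_predicate   = x("vocab:discussesAsDerivedByTextMining"),
    provenance_marker   = x("vocab:TextMinedCooccurrence"),
    title_predicate     = x("dcterms:title"),
    date_predicate      = x("dcterms:date"),
    journal_link        = x("dcterms:isPartOf"),
    journal_name        = x("prism:publicationName"),
    issn_predicate      = x("prism:issn"),
    author_link         = x("dcterms:creator"),
    name_predicate      = x("vocab:hasName"),
    mesh_predicate      = x("dcterms:subject"),
    grant_link          = x("frapo:isSupportedBy"),
    grant_number        = x("frapo:hasGrantNumber"),
    agency_link         = x("frapo:hasFundingAgency"),
    review_class        = x("vocab:ReviewArticle"),
    pmc_predicate       = x("vocab:hasPMCID"),
    role_predicate      = x("obo:RO_0000087"),
    fda_role            = x("vocab:FDAApprovedDrugs"),
    gene_symbol_pred    = x("bao:BAO_0002870"),
    organism_predicate  = x("up:organism"),
    pref_label          = x("skos:prefLabel")
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(profile))
    if (length(unknown)) {
      abort_input("unknown predicate_profile field '%s'", unknown[1L])
    }
    expand1 <- function(v) {
      vapply(v, function(y) if (grepl("^https?://", y)) y else ns_expand(y, ns),
             character(1))
    }
    for (nm in names(overrides)) {
      v <- expand1(overrides[[nm]])
      if (nm == "association_classes") {
        if (!setequal(names(v), PAIR_CLASSES)) {
          abort_input("association_classes must cover all six pair classes")
        }
        v <- v[PAIR_CLASSES]
      } else {
        names(v) <- NULL
      }
      profile[[nm]] <- v
    }
  }
  structure(profile, ns = ns, class = "predicate_profile")
}
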