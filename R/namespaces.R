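#' Default namespace table
#'
#' Prefix-to-IRI mappings for every vocabulary and subdomain base the
#' co-occurrence graph uses: the PubChem-style entity subdomains
#' (`compound`, `disease`, `gene`, `taxonomy`), the reference-metadata
#' subdomains (`reference`, `journal`, `author`, `grant`, `organization`),
#' the `cooccurrence` subdomain holding the reified association nodes, and
#' the external vocabularies (SIO, BAO, OBO/RO, UniProt core, SKOS, DCMI
#' terms, PRISM, FRAPO) plus `rdf`, `xsd` and `sh` (SHACL).
#'
#' @param overrides named character vector of prefix -> namespace IRI pairs
#'   that replace or extend the defaults.
#' @return named character vector; every IRI ends in `/` or `#`.
#' @examples
#' ns <- namespace_table()
#' ns[["compound"]]
#' @export
namespace_table <- function(overrides = NULL) {
  ns <- c(
    bao          = "http://www.bioassayontology.org/bao#",
    compound     = "http://rdf.ncbi.nlm.nih.gov/pubchem/compound/",
    dcterms      = "http://purl.org/dc/terms/",
    disease      = "http://rdf.ncbi.nlm.nih.gov/pubchem/disease/",
    frapo        = "http://purl.org/cerif/frapo/",
    gene         = "http://rdf.ncbi.nlm.nih.gov/pubchem/gene/",
    obo          = "http://purl.obolibrary.org/obo/",
    prism        = "http://prismstandard.org/namespaces/basic/3.0/",
    rdf          = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    sio          = "http://semanticscience.org/resource/",
    skos         = "http://www.w3.org/2004/02/skos/core#",
    taxonomy     = "http://rdf.ncbi.nlm.nih.gov/pubchem/taxonomy/",
    up           = "http://purl.uniprot.org/core/",
    vocab        = "http://rdf.ncbi.nlm.nih.gov/pubchem/vocabulary#",
    reference    = "http://rdf.ncbi.nlm.nih.gov/pubchem/reference/",
    journal      = "http://rdf.ncbi.nlm.nih.gov/pubchem/journal/",
    author       = "http://rdf.ncbi.nlm.nih.gov/pubchem/author/",
    grant        = "http://rdf.ncbi.nlm.nih.gov/pubchem/grant/",
    organization = "http://rdf.ncbi.nlm.nih.gov/pubchem/organization/",
    cooccurrence = "http://rdf.ncbi.nlm.nih.gov/pubchem/cooccurrence/",
    sh           = "http://www.w3.org/ns/shacl#",
    xsd          = "http://www.w3.org/2001/XMLSchema#"
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abort_input("namespace overrides must be a named character vector")
    }
    ns[names(overrides)] <- overrides
  }
  if (anyDuplicated(names(ns))) abort_input("namespace prefixes must be unique")
  bad <- !grepl("[/#]$", ns)
  if (any(bad)) {
    abort_input("namespace IRI for prefix '%s' must end in '/' or '#'",
                names(ns)[bad][1L])
  }
  ns
}

# expand "prefix:local" against a namespace table
ns_expand <- function(curie, ns = namespace_table()) {
  vapply(curie, function(x) {
    parts <- regmatches(x, regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", x))[[1]]
    if (length(parts) != 3L || !parts[2L] %in% names(ns)) {
      abort_input("cannot expand CURIE '%s': unknown prefix", x)
    }
    paste0(ns[[parts[2L]]], parts[3L])
  }, character(1), USE.NAMES = FALSE)
}

# compact an absolute IRI to prefix:local when a namespace matches
ns_compact <- function(iri, ns = namespace_table()) {
  ord <- order(nchar(ns), decreasing = TRUE)
  pre <- names(ns)[ord]
  base <- unname(ns)[ord]
  vapply(iri, function(x) {
    for (i in seq_along(base)) {
      if (startsWith(x, base[i])) {
        return(paste0(pre[i], ":", substring(x, nchar(base[i]) + 1L)))
      }
    }
    x
  }, character(1), USE.NAMES = FALSE)
}

#' Turtle prefix block for a namespace table
#'
#' @param ns a [namespace_table()].
#' @return character vector of `@prefix` lines.
#' @export
turtle_prefix_block <- function(ns = namespace_table()) {
  sprintf("@prefix %s: <%s> .", names(ns), unname(ns))
}

# subdomain bases keyed by subdomain name (order matters for longest match)
subdomain_bases <- function(ns = namespace_table()) {
  ns[c("cooccurrence", "reference", "compound", "gene", "disease",
       "journal", "author", "grant", "organization", "taxonomy")]
}
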