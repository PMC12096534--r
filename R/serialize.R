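#' Serialize neighbor lists as reified co-occurrence triples
#'
#' Every co-occurrence record becomes one node carrying exactly five
#' triples under the default profile: an `rdf:type` to its pair-class
#' association class, `rdf:subject` and `rdf:object` links to the entity
#' IRIs, the serialized integer score via the score predicate ("has
#' value"), and a second `rdf:type` to the text-mining provenance marker.
#'
#' @param lists a [build_neighbor_lists()] result (or any tibble with
#'   columns `subject`, `object`, `pair_class`, `serialized_score`).
#' @param profile a [predicate_profile()].
#' @param ns a [namespace_table()].
#' @return triple table.
#' @export
serialize_cooccurrences <- function(lists, profile = predicate_profile(),
                                    ns = namespace_table()) {
  stopifnot(inherits(profile, "predicate_profile"))
  if (!nrow(lists)) return(empty_triples())
  missing <- setdiff(unique(lists$pair_class),
                     names(profile$association_classes))
  if (length(missing)) {
    abort_input("no association class configured for pair class '%s'",
                missing[1L])
  }
  rdf <- ns[["rdf"]]
  node <- mint_cooccurrence_uri(lists$subject, lists$object, ns)
  bind_rows(
    triple_iri(node, paste0(rdf, "type"),
               unname(profile$association_classes[lists$pair_class])),
    triple_iri(node, paste0(rdf, "subject"),
               mint_entity_uri(lists$subject, ns)),
    triple_iri(node, paste0(rdf, "object"),
               mint_entity_uri(lists$object, ns)),
    triple_lit(node, profile$score_predicate, lists$serialized_score,
               XSD_INTEGER),
    triple_iri(node, paste0(rdf, "type"), profile$provenance_marker)
  )
}

journal_iri <- function(name, ns) paste0(ns[["journal"]], pct_encode(name))
author_iri <- function(name, ns) paste0(ns[["author"]], pct_encode(name))
organization_iri <- function(name, ns) {
  paste0(ns[["organization"]], pct_encode(name))
}
grant_iri <- function(number, ns) paste0(ns[["grant"]], pct_encode(number))
reference_iri <- function(ref_id, ns) {
  paste0(ns[["reference"]], "PMID", ref_id)
}

#' Serialize reference records and their metadata
#'
#' Each reference node links to its mentioned entities through the
#' text-mining mention predicate and to its metadata: title and date
#' (DCMI), journal node with name/ISSN (PRISM), author nodes, grant nodes
#' carrying grant number and funding agency (FRAPO), MeSH subject
#' headings, a review-article class assertion, and the PMC id when the
#' full text is freely available. A grantless funding acknowledgment
#' yields a direct reference-to-agency triple with no grant node.
#'
#' @param records list of [reference_record()]s.
#' @param profile a [predicate_profile()].
#' @param ns a [namespace_table()].
#' @return triple table.
#' @export
serialize_references <- function(records, profile = predicate_profile(),
                                 ns = namespace_table()) {
  validate_corpus(records)
  rdf <- ns[["rdf"]]
  out <- lapply(records, function(r) {
    ref <- reference_iri(r$ref_id, ns)
    jrn <- journal_iri(r$journal, ns)
    tr <- list(
      triple_iri(rep(ref, length(r$mentions)), profile$mention_predicate,
                 mint_entity_uri(r$mentions, ns)),
      triple_lit(ref, profile$title_predicate, r$title),
      triple_lit(ref, profile$date_predicate, format(r$date), XSD_DATE),
      triple_iri(ref, profile$journal_link, jrn),
      triple_lit(jrn, profile$journal_name, r$journal)
    )
    if (!is.na(r$issn)) {
      tr <- c(tr, list(triple_lit(jrn, profile$issn_predicate, r$issn)))
    }
    if (length(r$authors)) {
      au <- author_iri(r$authors, ns)
      tr <- c(tr, list(triple_iri(rep(ref, length(au)),
                                  profile$author_link, au),
                       triple_lit(au, profile$name_predicate, r$authors)))
    }
    for (g in r$grants) {
      org <- organization_iri(g$agency, ns)
      tr <- c(tr, list(triple_lit(org, profile$name_predicate, g$agency)))
      if (is.na(g$number)) {
        # agency acknowledged without a grant number: direct link
        tr <- c(tr, list(triple_iri(ref, profile$agency_link, org)))
      } else {
        gr <- grant_iri(g$number, ns)
        tr <- c(tr, list(
          triple_iri(ref, profile$grant_link, gr),
          triple_lit(gr, profile$grant_number, g$number),
          triple_iri(gr, profile$agency_link, org)
        ))
      }
    }
    if (length(r$mesh_headings)) {
      tr <- c(tr, list(triple_lit(rep(ref, length(r$mesh_headings)),
                                  profile$mesh_predicate, r$mesh_headings)))
    }
    if (r$is_review) {
      tr <- c(tr, list(triple_iri(ref, paste0(rdf, "type"),
                                  profile$review_class)))
    }
    if (!is.na(r$pmc_id)) {
      tr <- c(tr, list(triple_lit(ref, profile$pmc_predicate, r$pmc_id)))
    }
    bind_rows(tr)
  })
  normalize_triples(bind_rows(out))
}

#' Serialize entity annotations
#'
#' Disease and compound preferred labels (SKOS prefLabel), compound role
#' assertions ("has role"), and species-specific gene records: each
#' numbered gene record node links to its gene-symbol IRI ("has gene
#' symbol"), its organism taxon IRI, and its preferred name.
#'
#' @param annotations an [entity_annotations()].
#' @param profile a [predicate_profile()].
#' @param ns a [namespace_table()].
#' @return triple table.
#' @export
serialize_entities <- function(annotations, profile = predicate_profile(),
                               ns = namespace_table()) {
  stopifnot(inherits(annotations, "entity_annotations"))
  tr <- list()
  dl <- annotations$disease_labels
  if (length(dl)) {
    tr <- c(tr, list(triple_lit(
      mint_entity_uri(paste0("disease:", names(dl)), ns),
      profile$pref_label, unname(dl))))
  }
  cl <- annotations$compound_labels
  if (length(cl)) {
    tr <- c(tr, list(triple_lit(
      mint_entity_uri(paste0("compound:", names(cl)), ns),
      profile$pref_label, unname(cl))))
  }
  cr <- annotations$compound_roles
  if (nrow(cr)) {
    tr <- c(tr, list(triple_iri(
      mint_entity_uri(paste0("compound:", cr$cid), ns),
      profile$role_predicate,
      ns_expand(paste0("vocab:", cr$role), ns))))
  }
  gr <- annotations$gene_records
  if (nrow(gr)) {
    gid <- paste0(ns[["gene"]], "GID", gr$gid)
    tr <- c(tr, list(
      triple_iri(gid, profile$gene_symbol_pred,
                 mint_entity_uri(paste0("gene:", gr$symbol), ns)),
      triple_iri(gid, profile$organism_predicate,
                 paste0(ns[["taxonomy"]], "TAXID", gr$taxon)),
      triple_lit(gid, profile$pref_label, gr$name)
    ))
  }
  if (!length(tr)) return(empty_triples())
  normalize_triples(bind_rows(tr))
}

SUBDOMAINS <- c("cooccurrence", "reference", "compound", "gene", "disease",
                "journal", "author", "grant", "organization", "book")

#' Partition triples into a graph bundle
#'
#' A subdomain holds all triples sharing one subject entity type; every
#' triple lands in exactly one subdomain, keyed by the namespace of its
#' subject IRI. The `book` subdomain is accepted for interface parity but
#' never populated by this package.
#'
#' @param tr triple table.
#' @param ns a [namespace_table()].
#' @return named list of triple tables, class `graph_bundle`.
#' @export
graph_bundle <- function(tr, ns = namespace_table()) {
  tr <- normalize_triples(tr)
  bases <- subdomain_bases(ns)
  sub <- rep(NA_character_, nrow(tr))
  for (nm in names(bases)) {
    hit <- is.na(sub) & startsWith(tr$s, bases[[nm]])
    sub[hit] <- nm
  }
  if (anyNA(sub)) {
    abort_input("subject IRI '%s' belongs to no known subdomain",
                tr$s[is.na(sub)][1L])
  }
  out <- lapply(SUBDOMAINS, function(nm) {
    tr[sub == nm, , drop = FALSE]
  })
  names(out) <- SUBDOMAINS
  structure(out, ns = ns, class = "graph_bundle")
}

#' @export
print.graph_bundle <- function(x, ...) {
  counts <- vapply(x, nrow, integer(1))
  cat("<graph_bundle>\n")
  for (nm in names(x)[counts > 0L]) {
    cat(sprintf("  %-13s %6d triple(s)\n", nm, counts[[nm]]))
  }
  invisible(x)
}

bundle_triples <- function(bundle) {
  stopifnot(inherits(bundle, "graph_bundle"))
  normalize_triples(bind_rows(unclass(bundle)))
}

#' Build the full graph bundle for a corpus
#'
#' Runs scoring, neighbor-list truncation and all three serializers, and
#' partitions the result by subdomain.
#'
#' @param records list of [reference_record()]s.
#' @param annotations optional [entity_annotations()].
#' @param params a [scoring_params()].
#' @param profile a [predicate_profile()].
#' @param ns a [namespace_table()].
#' @return a [graph_bundle()].
#' @export
build_bundle <- function(records, annotations = NULL,
                         params = scoring_params(),
                         profile = predicate_profile(ns),
                         ns = namespace_table()) {
  lists <- build_neighbor_lists(records, params, ns)
  tr <- bind_rows(
    serialize_cooccurrences(lists, profile, ns),
    serialize_references(records, profile, ns),
    if (!is.null(annotations)) serialize_entities(annotations, profile, ns)
  )
  graph_bundle(tr, ns)
}

#' Write a graph bundle to disk, partitioned by subdomain
#'
#' Mirrors the bulk-download layout: each non-empty subdomain gets its own
#' subdirectory holding one Turtle or N-Triples file. Files are
#' canonically sorted, so identical bundles write byte-identical trees.
#'
#' @param bundle a [graph_bundle()].
#' @param dir output directory.
#' @param format `"turtle"` or `"ntriples"`.
#' @return character vector of written files, invisibly.
#' @export
write_bundle <- function(bundle, dir, format = c("turtle", "ntriples")) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "graph_bundle"))
  ns <- attr(bundle, "ns")
  ext <- c(turtle = "ttl", ntriples = "nt")[[format]]
  written <- character()
  for (nm in names(bundle)) {
    tr <- bundle[[nm]]
    if (!nrow(tr)) next
    sub <- file.path(dir, nm)
    dir.create(sub, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(sub, paste0(nm, ".", ext))
    if (format == "turtle") write_turtle(tr, path, ns)
    else write_ntriples(tr, path)
    written <- c(written, path)
  }
  invisible(written)
}

#' Read a graph bundle from a subdomain directory tree
#'
#' @param dir directory written by [write_bundle()].
#' @param ns a [namespace_table()].
#' @return a [graph_bundle()].
#' @export
read_bundle <- function(dir, ns = namespace_table()) {
  files <- list.files(dir, pattern = "\\.(ttl|nt)$", recursive = TRUE,
                      full.names = TRUE)
  # only subdomain subdirectories belong to the bundle; top-level files
  # (e.g. an emitted shapes graph) are not data
  files <- files[basename(dirname(files)) %in% SUBDOMAINS]
  if (!length(files)) abort_input("no RDF files found under '%s'", dir)
  tr <- bind_rows(lapply(files, function(f) {
    if (grepl("\\.ttl$", f)) parse_turtle(f) else parse_ntriples(f)
  }))
  graph_bundle(tr, ns)
}
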