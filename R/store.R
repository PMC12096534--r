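#' Load a graph bundle into an in-memory RDF store
#'
#' The store is the query surface of the package: all use-case operations
#' run as triple-pattern joins against it, never against the pre-RDF
#' records it was built from.
#'
#' @param bundle a [graph_bundle()], a directory written by
#'   [write_bundle()], or a bare triple table.
#' @param profile the [predicate_profile()] the bundle was serialized
#'   with (queries need the association classes and predicates).
#' @param ns a [namespace_table()].
#' @return an object of class `cooc_store`.
#' @export
load_store <- function(bundle, profile = predicate_profile(ns),
                       ns = namespace_table()) {
  tr <- if (inherits(bundle, "graph_bundle")) {
    bundle_triples(bundle)
  } else if (is.character(bundle) && length(bundle) == 1L) {
    bundle_triples(read_bundle(bundle, ns))
  } else {
    normalize_triples(bundle)
  }
  structure(list(triples = tr, profile = profile, ns = ns),
            class = "cooc_store")
}

#' @export
print.cooc_store <- function(x, ...) {
  cat(sprintf("<cooc_store: %d triple(s)>\n", nrow(x$triples)))
  invisible(x)
}

#' Number of triples in a store
#'
#' @param store a [load_store()] result.
#' @return integer triple count.
#' @export
store_size <- function(store) {
  stopifnot(inherits(store, "cooc_store"))
  nrow(store$triples)
}

# triple-pattern match: NULL = wildcard; returns the matching rows
tp <- function(store, s = NULL, p = NULL, o = NULL) {
  tr <- store$triples
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(s)) keep <- keep & tr$s %in% s
  if (!is.null(p)) keep <- keep & tr$p %in% p
  if (!is.null(o)) keep <- keep & tr$o %in% o & !tr$lit
  tr[keep, , drop = FALSE]
}

tp_lit <- function(store, s = NULL, p = NULL) {
  tr <- store$triples
  keep <- tr$lit
  if (!is.null(s)) keep <- keep & tr$s %in% s
  if (!is.null(p)) keep <- keep & tr$p %in% p
  tr[keep, , drop = FALSE]
}

rdf_type_iri <- function(store) paste0(store$ns[["rdf"]], "type")

# serialized co-occurrence records anchored at `subject_iri` whose object
# is of `kind`, as a tibble(object_iri, score), query-ordered
store_neighbors <- function(store, subject_iri, kind, anchor_kind) {
  profile <- store$profile
  cls <- profile$association_classes[[pair_class_of(anchor_kind, kind)]]
  nodes <- tp(store, p = paste0(store$ns[["rdf"]], "subject"),
              o = subject_iri)$s
  nodes <- intersect(nodes, tp(store, s = nodes, p = rdf_type_iri(store),
                               o = cls)$s)
  if (!length(nodes)) {
    return(tibble(node = character(), object_iri = character(),
                  score = integer()))
  }
  obj <- tp(store, s = nodes, p = paste0(store$ns[["rdf"]], "object"))
  # same-kind classes type both directions; keep objects of the asked kind
  obj <- obj[startsWith(obj$o, store$ns[[kind]]), , drop = FALSE]
  sc <- tp_lit(store, s = obj$s, p = profile$score_predicate)
  out <- inner_join(select(obj, node = "s", object_iri = "o"),
                    select(sc, node = "s", score = "o"), by = "node")
  out <- mutate(out, score = as.integer(.data$score))
  arrange(out, dplyr::desc(.data$score), .data$object_iri)
}

# prefLabel lookup for a set of IRIs -> named character
store_labels <- function(store, iris) {
  lab <- tp_lit(store, s = iris, p = store$profile$pref_label)
  setNames(lab$o, lab$s)
}

ref_id_from_iri <- function(iri, ns) {
  as.integer(sub("^PMID", "", substring(iri, nchar(ns[["reference"]]) + 1L)))
}
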