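MUTATION_OPERATORS <- c("drop_subject", "drop_object", "duplicate_score",
                        "noninteger_score", "uppercase_gene_iri",
                        "unknown_association_class")

#' Inject a single schema defect into a graph bundle
#'
#' Defect-injection operators for exercising the SHACL validator; each
#' returns a bundle differing from the input by exactly the targeted
#' defect. The affected node is chosen deterministically from the seed.
#'
#' Operators: `drop_subject` / `drop_object` remove one reification link
#' from a co-occurrence node; `duplicate_score` adds a second, different
#' score value; `noninteger_score` rewrites a score literal to a decimal;
#' `uppercase_gene_iri` rewrites one gene entity IRI occurrence to
#' contain an uppercase letter; `unknown_association_class` retypes one
#' co-occurrence node to an unconfigured class.
#'
#' @param bundle a [graph_bundle()].
#' @param operator one of `r paste0('"', MUTATION_OPERATORS, '"', collapse = ", ")`.
#' @param seed integer seed selecting the mutated node.
#' @param profile the bundle's [predicate_profile()].
#' @param ns a [namespace_table()]; defaults to the bundle's own.
#' @return the mutated [graph_bundle()].
#' @export
mutate_bundle <- function(bundle, operator, seed = 1L,
                          profile = predicate_profile(ns),
                          ns = attr(bundle, "ns") %||% namespace_table()) {
  stopifnot(inherits(bundle, "graph_bundle"))
  operator <- match.arg(operator, MUTATION_OPERATORS)
  tr <- bundle_triples(bundle)
  rdf <- ns[["rdf"]]
  pick <- function(x) {
    x <- sort(unique(x))
    if (!length(x)) {
      abort_input("operator '%s' is inapplicable to this bundle", operator)
    }
    x[with_seed(seed, sample.int(length(x), 1L))]
  }
  if (operator %in% c("drop_subject", "drop_object")) {
    pred <- paste0(rdf, if (operator == "drop_subject") "subject" else
      "object")
    node <- pick(tr$s[tr$p == pred &
                        startsWith(tr$s, ns[["cooccurrence"]])])
    drop <- which(tr$s == node & tr$p == pred)
    tr <- tr[-drop, , drop = FALSE]
  } else if (operator == "duplicate_score") {
    node <- pick(tr$s[tr$p == profile$score_predicate])
    old <- tr$o[tr$s == node & tr$p == profile$score_predicate][1L]
    tr <- bind_rows(tr, triple_lit(node, profile$score_predicate,
                                   as.integer(old) + 1L, XSD_INTEGER))
  } else if (operator == "noninteger_score") {
    node <- pick(tr$s[tr$p == profile$score_predicate])
    i <- which(tr$s == node & tr$p == profile$score_predicate)[1L]
    tr$o[i] <- paste0(tr$o[i], ".5")
    tr$dtype[i] <- XSD_DECIMAL
  } else if (operator == "uppercase_gene_iri") {
    gene_base <- ns[["gene"]]
    cand <- which(!tr$lit & startsWith(tr$o, gene_base) &
                    !grepl("/GID[0-9]+$", tr$o) &
                    grepl("[a-z]", substring(tr$o, nchar(gene_base) + 1L)) &
                    tr$p %in% c(paste0(rdf, "subject"), paste0(rdf, "object"),
                                profile$mention_predicate))
    if (!length(cand)) {
      abort_input("operator 'uppercase_gene_iri' is inapplicable to this bundle")
    }
    i <- cand[with_seed(seed, sample.int(length(cand), 1L))]
    local <- substring(tr$o[i], nchar(gene_base) + 1L)
    tr$o[i] <- paste0(gene_base, toupper(local))
  } else {  # unknown_association_class
    classes <- profile$association_classes
    cand <- which(tr$p == paste0(rdf, "type") & tr$o %in% classes)
    if (!length(cand)) {
      abort_input("operator 'unknown_association_class' is inapplicable to this bundle")
    }
    i <- cand[with_seed(seed, sample.int(length(cand), 1L))]
    tr$o[i] <- ns_expand("vocab:UnknownAssociation", ns)
  }
  graph_bundle(tr, ns)
}
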