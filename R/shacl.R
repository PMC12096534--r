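#' Emit the SHACL shapes describing the graph model
#'
#' Three node shapes encode the model's contract:
#'
#' * every co-occurrence node (targeted as subject of `rdf:subject` or
#'   `rdf:object`) carries exactly one `rdf:subject`, exactly one
#'   `rdf:object`, exactly one non-negative integer score, and at least
#'   one `rdf:type` drawn from the configured association classes;
#' * every reference node (targeted as subject of the title predicate)
#'   carries at most one title and at most one date;
#' * every entity IRI reachable as `rdf:subject` / `rdf:object` of a
#'   co-occurrence node or as object of the mention predicate matches the
#'   entity IRI grammar: `CID` + digits, `DZID` + digits, or a gene local
#'   name free of bare uppercase letters (percent-escape hex octets are
#'   allowed).
#'
#' The shapes graph is itself plain RDF (list nodes are skolemized) and
#' can be written with [write_shapes()].
#'
#' @param profile a [predicate_profile()].
#' @param ns a [namespace_table()].
#' @return an object of class `shape_set` wrapping the shapes triples.
#' @export
emit_shapes <- function(profile = predicate_profile(),
                        ns = namespace_table()) {
  stopifnot(inherits(profile, "predicate_profile"))
  sh <- ns[["sh"]]
  rdf <- ns[["rdf"]]
  vocab <- ns[["vocab"]]
  xsd_int <- XSD_INTEGER

  shape <- function(name) paste0(vocab, name)
  lit_int <- function(s, p, v) triple_lit(s, p, v, xsd_int)

  cooc <- shape("CooccurrenceShape")
  ref <- shape("ReferenceShape")
  ent <- shape("EntityIRIShape")
  class_list <- shape("CooccurrenceShape-classes")

  pshape <- function(node, path, min = NULL, max = NULL, dtype = NULL,
                     node_kind = NULL, min_inclusive = NULL) {
    tr <- list(triple_iri(node, paste0(sh, "path"), path))
    if (!is.null(min)) tr <- c(tr, list(lit_int(node, paste0(sh, "minCount"), min)))
    if (!is.null(max)) tr <- c(tr, list(lit_int(node, paste0(sh, "maxCount"), max)))
    if (!is.null(dtype)) tr <- c(tr, list(triple_iri(node, paste0(sh, "datatype"), dtype)))
    if (!is.null(node_kind)) tr <- c(tr, list(triple_iri(node, paste0(sh, "nodeKind"), node_kind)))
    if (!is.null(min_inclusive)) tr <- c(tr, list(lit_int(node, paste0(sh, "minInclusive"), min_inclusive)))
    bind_rows(tr)
  }

  gene_local <- "(?:[^A-Z%]|%[0-9A-F]{2})+"
  entity_pattern <- paste0(
    "^(?:", gsub("([.])", "\\\\\\1", ns[["compound"]]), "CID[1-9][0-9]*",
    "|", gsub("([.])", "\\\\\\1", ns[["disease"]]), "DZID[1-9][0-9]*",
    "|", gsub("([.])", "\\\\\\1", ns[["gene"]]), gene_local, ")$")

  tr <- bind_rows(
    # --- co-occurrence node shape -------------------------------------
    triple_iri(cooc, paste0(rdf, "type"), paste0(sh, "NodeShape")),
    triple_iri(cooc, paste0(sh, "targetSubjectsOf"), paste0(rdf, "subject")),
    triple_iri(cooc, paste0(sh, "targetSubjectsOf"), paste0(rdf, "object")),
    triple_iri(cooc, paste0(sh, "property"), paste0(cooc, "-subject")),
    triple_iri(cooc, paste0(sh, "property"), paste0(cooc, "-object")),
    triple_iri(cooc, paste0(sh, "property"), paste0(cooc, "-score")),
    triple_iri(cooc, paste0(sh, "property"), paste0(cooc, "-class")),
    pshape(paste0(cooc, "-subject"), paste0(rdf, "subject"), min = 1, max = 1,
           node_kind = paste0(sh, "IRI")),
    pshape(paste0(cooc, "-object"), paste0(rdf, "object"), min = 1, max = 1,
           node_kind = paste0(sh, "IRI")),
    pshape(paste0(cooc, "-score"), profile$score_predicate, min = 1, max = 1,
           dtype = xsd_int, min_inclusive = 0),
    # at least one rdf:type among the configured association classes
    triple_iri(paste0(cooc, "-class"), paste0(sh, "path"),
               paste0(rdf, "type")),
    triple_iri(paste0(cooc, "-class"), paste0(sh, "qualifiedValueShape"),
               paste0(cooc, "-class-values")),
    lit_int(paste0(cooc, "-class"), paste0(sh, "qualifiedMinCount"), 1),
    triple_iri(paste0(cooc, "-class-values"), paste0(sh, "in"), class_list),
    rdf_list_triples(class_list, unname(profile$association_classes), ns),
    # --- reference node shape -----------------------------------------
    triple_iri(ref, paste0(rdf, "type"), paste0(sh, "NodeShape")),
    triple_iri(ref, paste0(sh, "targetSubjectsOf"), profile$title_predicate),
    triple_iri(ref, paste0(sh, "property"), paste0(ref, "-title")),
    triple_iri(ref, paste0(sh, "property"), paste0(ref, "-date")),
    pshape(paste0(ref, "-title"), profile$title_predicate, max = 1),
    pshape(paste0(ref, "-date"), profile$date_predicate, max = 1),
    # --- entity IRI pattern shape -------------------------------------
    triple_iri(ent, paste0(rdf, "type"), paste0(sh, "NodeShape")),
    triple_iri(ent, paste0(sh, "targetObjectsOf"), paste0(rdf, "subject")),
    triple_iri(ent, paste0(sh, "targetObjectsOf"), paste0(rdf, "object")),
    triple_iri(ent, paste0(sh, "targetObjectsOf"), profile$mention_predicate),
    triple_lit(ent, paste0(sh, "pattern"), entity_pattern),
    triple_iri(ent, paste0(sh, "nodeKind"), paste0(sh, "IRI"))
  )
  structure(list(triples = normalize_triples(tr)),
            ns = ns, class = "shape_set")
}

#' @export
print.shape_set <- function(x, ...) {
  cat(sprintf("<shape_set: %d triple(s)>\n", nrow(x$triples)))
  invisible(x)
}

#' Write a shape set as Turtle
#'
#' @param shapes a [emit_shapes()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shapes <- function(shapes, path) {
  stopifnot(inherits(shapes, "shape_set"))
  write_turtle(shapes$triples, path, attr(shapes, "ns"))
}

#' Read a shape set from a Turtle file
#'
#' @param path file written by [write_shapes()].
#' @param ns a [namespace_table()].
#' @return a `shape_set`.
#' @export
read_shapes <- function(path, ns = namespace_table()) {
  structure(list(triples = parse_turtle(path)), ns = ns, class = "shape_set")
}

#' Validate a graph bundle against SHACL shapes
#'
#' Interprets the constraint vocabulary used by [emit_shapes()]:
#' `sh:targetClass` / `sh:targetSubjectsOf` / `sh:targetObjectsOf`
#' targeting, and the `sh:minCount`, `sh:maxCount`, `sh:datatype`,
#' `sh:nodeKind`, `sh:minInclusive`, `sh:pattern`, and
#' `sh:qualifiedValueShape` + `sh:in` constraint components. Violation
#' messages name the focus node and its subdomain.
#'
#' @param bundle a [graph_bundle()] (or a bare triple table).
#' @param shapes a `shape_set`.
#' @return `list(conforms = logical, violations = tibble(focus,
#'   constraint, message))`, class `validation_report`.
#' @export
validate_bundle <- function(bundle, shapes) {
  stopifnot(inherits(shapes, "shape_set"))
  data <- if (inherits(bundle, "graph_bundle")) {
    bundle_triples(bundle)
  } else {
    normalize_triples(bundle)
  }
  ns <- attr(shapes, "ns") %||% namespace_table()
  sh <- ns[["sh"]]
  rdf <- ns[["rdf"]]
  stg <- shapes$triples

  sobj <- function(s, p) stg$o[stg$s == s & stg$p == p]
  violations <- list()
  note <- function(focus, constraint, message) {
    violations[[length(violations) + 1L]] <<- tibble(
      focus = focus, constraint = constraint,
      message = sprintf("%s [subdomain: %s]", message,
                        subdomain_of(focus, ns)))
  }

  node_shapes <- unique(stg$s[stg$p == paste0(rdf, "type") &
                                stg$o == paste0(sh, "NodeShape")])
  for (shape in node_shapes) {
    focus <- shape_targets(shape, stg, data, sh, rdf)
    if (!length(focus)) next
    # node-level constraints
    pat <- sobj(shape, paste0(sh, "pattern"))
    if (length(pat)) {
      bad <- focus[!grepl(pat, focus, perl = TRUE)]
      for (f in bad) note(f, "sh:pattern",
                          sprintf("node '%s' does not match pattern", f))
    }
    # focus nodes are always IRIs here (targets are drawn from IRI terms)
    for (pnode in sobj(shape, paste0(sh, "property"))) {
      check_property_shape(pnode, focus, stg, data, sh, note)
    }
  }
  out <- if (length(violations)) bind_rows(violations) else
    tibble(focus = character(), constraint = character(),
           message = character())
  structure(list(conforms = nrow(out) == 0L, violations = out),
            class = "validation_report")
}

shape_targets <- function(shape, stg, data, sh, rdf) {
  sobj <- function(p) stg$o[stg$s == shape & stg$p == paste0(sh, p)]
  focus <- character()
  for (p in sobj("targetSubjectsOf")) {
    focus <- c(focus, data$s[data$p == p])
  }
  for (p in sobj("targetObjectsOf")) {
    focus <- c(focus, data$o[data$p == p & !data$lit])
  }
  for (cls in sobj("targetClass")) {
    focus <- c(focus, data$s[data$p == paste0(rdf, "type") & data$o == cls])
  }
  unique(focus)
}

check_property_shape <- function(pnode, focus, stg, data, sh, note) {
  sobj <- function(p) stg$o[stg$s == pnode & stg$p == paste0(sh, p)]
  path <- sobj("path")
  if (length(path) != 1L) return(invisible())
  min_count <- as.integer(sobj("minCount"))
  max_count <- as.integer(sobj("maxCount"))
  dtype <- sobj("datatype")
  node_kind <- sobj("nodeKind")
  min_incl <- as.numeric(sobj("minInclusive"))
  qshape <- sobj("qualifiedValueShape")
  qmin <- as.integer(sobj("qualifiedMinCount"))

  hits <- data[data$p == path & data$s %in% focus, , drop = FALSE]
  counts <- table(factor(hits$s, levels = focus))
  if (length(min_count)) {
    for (f in focus[counts < min_count]) {
      note(f, "sh:minCount",
           sprintf("node '%s' has %d value(s) for <%s>, needs >= %d",
                   f, counts[[f]], path, min_count))
    }
  }
  if (length(max_count)) {
    for (f in focus[counts > max_count]) {
      note(f, "sh:maxCount",
           sprintf("node '%s' has %d value(s) for <%s>, allows <= %d",
                   f, counts[[f]], path, max_count))
    }
  }
  if (length(dtype) && nrow(hits)) {
    ok <- hits$lit & !is.na(hits$dtype) & hits$dtype == dtype &
      (dtype != XSD_INTEGER | grepl("^-?[0-9]+$", hits$o))
    for (i in which(!ok)) {
      note(hits$s[i], "sh:datatype",
           sprintf("value '%s' of <%s> on node '%s' is not a %s literal",
                   hits$o[i], path, hits$s[i], dtype))
    }
  }
  if (length(node_kind) && nrow(hits) && endsWith(node_kind, "IRI")) {
    for (i in which(hits$lit)) {
      note(hits$s[i], "sh:nodeKind",
           sprintf("value '%s' of <%s> on node '%s' must be an IRI",
                   hits$o[i], path, hits$s[i]))
    }
  }
  if (length(min_incl) && nrow(hits)) {
    num <- suppressWarnings(as.numeric(hits$o))
    for (i in which(!is.na(num) & num < min_incl)) {
      note(hits$s[i], "sh:minInclusive",
           sprintf("value %s of <%s> on node '%s' is below %s",
                   hits$o[i], path, hits$s[i], min_incl))
    }
  }
  if (length(qshape) && length(qmin)) {
    allowed <- shacl_in_values(qshape, stg, sh)
    ok_counts <- table(factor(hits$s[!hits$lit & hits$o %in% allowed],
                              levels = focus))
    for (f in focus[ok_counts < qmin]) {
      note(f, "sh:qualifiedMinCount",
           sprintf("node '%s' has %d value(s) of <%s> in the allowed set, needs >= %d",
                   f, ok_counts[[f]], path, qmin))
    }
  }
  invisible()
}

shacl_in_values <- function(qshape, stg, sh) {
  head <- stg$o[stg$s == qshape & stg$p == paste0(sh, "in")]
  if (length(head) != 1L) return(character())
  rdf_list_items(stg, head)
}

subdomain_of <- function(iri, ns) {
  bases <- subdomain_bases(ns)
  for (nm in names(bases)) {
    if (startsWith(iri, bases[[nm]])) return(nm)
  }
  "external"
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %s>\n",
              if (x$conforms) "conforms" else
                sprintf("%d violation(s)", nrow(x$violations))))
  if (!x$conforms) {
    for (i in seq_len(min(10L, nrow(x$violations)))) {
      cat(sprintf("  [%s] %s\n", x$violations$constraint[i],
                  x$violations$message[i]))
    }
    if (nrow(x$violations) > 10L) cat("  ...\n")
  }
  invisible(x)
}
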