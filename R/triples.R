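# In-memory RDF graph: a tibble with one row per triple.
#   s      subject IRI
#   p      predicate IRI
#   o      object: IRI text or literal lexical form
#   lit    TRUE when the object is a literal
#   dtype  literal datatype IRI (NA = plain xsd:string)
# Blank nodes are never emitted; every node is a skolem IRI, which keeps
# both writers line-oriented and the round-trip exact.

empty_triples <- function() {
  tibble(s = character(), p = character(), o = character(),
         lit = logical(), dtype = character())
}

triple_iri <- function(s, p, o) {
  if (!length(s)) return(empty_triples())
  tibble(s = s, p = p, o = o, lit = FALSE, dtype = NA_character_)
}

triple_lit <- function(s, p, o, dtype = NA_character_) {
  if (!length(s)) return(empty_triples())
  tibble(s = s, p = p, o = as.character(o), lit = TRUE, dtype = dtype)
}

XSD_INTEGER <- "http://www.w3.org/2001/XMLSchema#integer"
XSD_DATE <- "http://www.w3.org/2001/XMLSchema#date"
XSD_DECIMAL <- "http://www.w3.org/2001/XMLSchema#decimal"

# canonical deterministic ordering; also deduplicates (a graph is a set)
normalize_triples <- function(tr) {
  tr <- distinct(as_tibble(tr))
  arrange(tr, .data$s, .data$p, .data$lit, .data$o, .data$dtype)
}

same_triple_set <- function(a, b) {
  a <- normalize_triples(a)
  b <- normalize_triples(b)
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b),
                   check.attributes = FALSE))
}

escape_nt_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_nt_literal <- function(x) {
  out <- character(length(x))
  for (j in seq_along(x)) {
    cs <- strsplit(x[j], "", fixed = FALSE)[[1]]
    buf <- character(0)
    i <- 1L
    while (i <= length(cs)) {
      if (cs[i] == "\\" && i < length(cs)) {
        nxt <- cs[i + 1L]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"",
                             abort_input("bad escape '\\%s'", nxt)))
        i <- i + 2L
      } else {
        buf <- c(buf, cs[i])
        i <- i + 1L
      }
    }
    out[j] <- paste(buf, collapse = "")
  }
  out
}

format_nt_object <- function(tr) {
  ifelse(!tr$lit, paste0("<", tr$o, ">"),
         paste0("\"", escape_nt_literal(tr$o), "\"",
                ifelse(is.na(tr$dtype), "", paste0("^^<", tr$dtype, ">"))))
}

#' Write triples as N-Triples
#'
#' One statement per line, canonically sorted so identical graphs always
#' produce byte-identical files.
#'
#' @param tr triple table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(tr, path) {
  tr <- normalize_triples(tr)
  lines <- paste0("<", tr$s, "> <", tr$p, "> ", format_nt_object(tr), " .")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Parse an N-Triples file
#'
#' Reads the line-oriented subset this package emits (IRIs and typed or
#' plain literals; no blank nodes).
#'
#' @param path input file.
#' @return triple table.
#' @export
parse_ntriples <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parse_statement_lines(lines, resolve = identity, path = path)
}

parse_statement_lines <- function(lines, resolve, path) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_triples())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    m <- regexec("^(<[^>]*>|[A-Za-z][A-Za-z0-9]*:\\S*)\\s+(<[^>]*>|[A-Za-z][A-Za-z0-9]*:\\S*)\\s+(.*?)\\s*\\.$",
                 lines[i])
    parts <- regmatches(lines[i], m)[[1]]
    if (length(parts) != 4L) {
      abort_input("unparseable statement at %s line %d", path, i)
    }
    s <- resolve_term(parts[2L], resolve)
    p <- resolve_term(parts[3L], resolve)
    obj <- parse_object_term(parts[4L], resolve, path, i)
    out[[i]] <- tibble(s = s, p = p, o = obj$o, lit = obj$lit,
                       dtype = obj$dtype)
  }
  normalize_triples(bind_rows(out))
}

resolve_term <- function(tok, resolve) {
  if (startsWith(tok, "<")) sub("^<(.*)>$", "\\1", tok) else resolve(tok)
}

parse_object_term <- function(tok, resolve, path, i) {
  if (startsWith(tok, "\"")) {
    m <- regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^(<[^>]*>|[A-Za-z][A-Za-z0-9]*:\\S*))?$",
                 tok)
    parts <- regmatches(tok, m)[[1]]
    if (!length(parts)) {
      abort_input("unparseable literal at %s line %d", path, i)
    }
    dtype <- if (length(parts) >= 3L && nzchar(parts[3L])) {
      resolve_term(parts[3L], resolve)
    } else {
      NA_character_
    }
    list(o = unescape_nt_literal(parts[2L]), lit = TRUE, dtype = dtype)
  } else {
    list(o = resolve_term(tok, resolve), lit = FALSE, dtype = NA_character_)
  }
}

# Turtle local names are kept conservative: compact only when the local
# part is plainly safe, otherwise fall back to an absolute IRI
turtle_term <- function(iri, ns) {
  curie <- ns_compact(iri, ns)
  ok <- curie != iri &
    grepl("^[A-Za-z][A-Za-z0-9]*:[A-Za-z_][A-Za-z0-9_-]*$", curie)
  ifelse(ok, curie, paste0("<", iri, ">"))
}

#' Write triples as Turtle
#'
#' Emits the `@prefix` block from the namespace table, then one statement
#' per line (predicates and well-behaved IRIs compacted to CURIEs).
#'
#' @param tr triple table.
#' @param path output file.
#' @param ns a [namespace_table()].
#' @return `path`, invisibly.
#' @export
write_turtle <- function(tr, path, ns = namespace_table()) {
  tr <- normalize_triples(tr)
  dt <- rep("", nrow(tr))
  has_dt <- tr$lit & !is.na(tr$dtype)
  dt[has_dt] <- paste0("^^", turtle_term(tr$dtype[has_dt], ns))
  obj <- character(nrow(tr))
  obj[!tr$lit] <- turtle_term(tr$o[!tr$lit], ns)
  obj[tr$lit] <- paste0("\"", escape_nt_literal(tr$o[tr$lit]), "\"",
                        dt[tr$lit])
  lines <- c(turtle_prefix_block(ns), "",
             paste0(turtle_term(tr$s, ns), " ", turtle_term(tr$p, ns), " ",
                    obj, " ."))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Parse a Turtle file
#'
#' Reads the line-oriented Turtle this package emits: an `@prefix` block
#' followed by one statement per line.
#'
#' @param path input file.
#' @return triple table.
#' @export
parse_turtle <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  is_prefix <- grepl("^@prefix\\s", lines)
  prefixes <- character()
  for (ln in lines[is_prefix]) {
    m <- regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s+<([^>]*)>\\s*\\.$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3L) abort_input("bad @prefix line in %s", path)
    prefixes[parts[2L]] <- parts[3L]
  }
  resolve <- function(tok) {
    m <- regexec("^([A-Za-z][A-Za-z0-9]*):(.*)$", tok)
    parts <- regmatches(tok, m)[[1]]
    if (length(parts) != 3L || !parts[2L] %in% names(prefixes)) {
      abort_input("unknown prefix in term '%s' (%s)", tok, path)
    }
    paste0(prefixes[[parts[2L]]], parts[3L])
  }
  parse_statement_lines(lines[!is_prefix], resolve = resolve, path = path)
}

# skolem IRIs for RDF collections (sh:in lists)
rdf_list_triples <- function(head_iri, items_iri, ns = namespace_table()) {
  rdf <- ns[["rdf"]]
  n <- length(items_iri)
  nodes <- c(head_iri, paste0(head_iri, "-", seq_len(n)[-1L] - 1L))
  if (n == 0L) return(empty_triples())
  bind_rows(
    triple_iri(nodes, paste0(rdf, "first"), items_iri),
    triple_iri(nodes, paste0(rdf, "rest"),
               c(nodes[-1L], paste0(rdf, "nil")))
  )
}

# follow an rdf:first/rdf:rest chain in a triple table
rdf_list_items <- function(tr, head_iri, ns = namespace_table()) {
  rdf <- ns[["rdf"]]
  items <- character()
  node <- head_iri
  while (!identical(node, paste0(rdf, "nil"))) {
    first <- tr$o[tr$s == node & tr$p == paste0(rdf, "first")]
    rest <- tr$o[tr$s == node & tr$p == paste0(rdf, "rest")]
    if (length(first) != 1L || length(rest) != 1L) {
      abort_input("malformed RDF list at node '%s'", node)
    }
    items <- c(items, first)
    node <- rest
  }
  items
}
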