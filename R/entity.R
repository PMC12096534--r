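ENTITY_KINDS <- c("compound", "gene", "disease")

#' Canonicalize a gene symbol
#'
#' Gene symbols conflate orthologous genes across species whose printed
#' capitalization differs ("BRCA2" human, "Brca2" mouse, "brca2" zebrafish),
#' so the graph standardizes them to lowercase. Surrounding whitespace is
#' trimmed; all other characters (spaces, parentheses, "@", ...) pass
#' through untouched -- percent-encoding is an IRI-level concern handled by
#' [mint_entity_uri()].
#'
#' @param raw character vector of gene symbols.
#' @return lowercased symbols. Idempotent.
#' @examples
#' canonicalize_gene_symbol("BRCA2")
#' canonicalize_gene_symbol("L(3)MBT")
#' @export
canonicalize_gene_symbol <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L) {
    abort_input("gene symbol must be a non-empty character vector")
  }
  s <- trimws(raw)
  if (any(is.na(s)) || any(!nzchar(s))) {
    abort_input("gene symbol must be non-empty after trimming whitespace")
  }
  tolower(s)
}

#' Create a named-entity reference
#'
#' An `entity_ref` identifies one named entity of the graph: a compound by
#' its positive integer CID, a disease by its positive integer DZID, or a
#' gene by its canonical (lowercased) symbol. Equality is equality of
#' `(kind, local_id)`.
#'
#' @param kind one of `"compound"`, `"gene"`, `"disease"`.
#' @param local_id CID/DZID (coercible to positive integer) or gene symbol.
#' @return an object of class `entity_ref`.
#' @examples
#' entity_ref("compound", 3715)
#' entity_ref("gene", "BRCA2")   # canonicalized to "brca2"
#' @export
entity_ref <- function(kind, local_id) {
  kind <- match.arg(kind, ENTITY_KINDS)
  if (kind %in% c("compound", "disease")) {
    id <- suppressWarnings(as.numeric(local_id))
    if (length(id) != 1L || is.na(id) || id < 1 || id != as.integer(id) ||
        !grepl("^[0-9]+$", as.character(local_id))) {
      abort_input("%s local_id must be a positive integer, got '%s'",
                  kind, as.character(local_id))
    }
    local_id <- format(as.integer(id), scientific = FALSE)
  } else {
    local_id <- canonicalize_gene_symbol(as.character(local_id))
  }
  structure(list(kind = kind, local_id = local_id), class = "entity_ref")
}

#' @export
print.entity_ref <- function(x, ...) {
  cat(sprintf("<entity_ref %s:%s>\n", x$kind, x$local_id))
  invisible(x)
}

#' @export
format.entity_ref <- function(x, ...) entity_token(x)

#' @export
`==.entity_ref` <- function(e1, e2) {
  identical(entity_token(e1), entity_token(e2))
}

#' Entity tokens
#'
#' The compact text form `"kind:local_id"` (e.g. `"compound:3715"`,
#' `"gene:brca2"`) used in the corpus dialect and throughout mention sets.
#' `entity_token()` renders refs as tokens; `as_entity_ref()` parses a token
#' (or passes an `entity_ref` through), canonicalizing gene symbols.
#'
#' @param e an `entity_ref` or a token string.
#' @return `entity_token()`: character; `as_entity_ref()`: an `entity_ref`.
#' @examples
#' entity_token(entity_ref("gene", "BRCA2"))
#' as_entity_ref("disease:8173")
#' @export
entity_token <- function(e) {
  if (inherits(e, "entity_ref")) return(paste0(e$kind, ":", e$local_id))
  if (is.character(e)) return(vapply(e, canonical_token, character(1),
                                     USE.NAMES = FALSE))
  abort_input("cannot convert object of class '%s' to an entity token",
              class(e)[1L])
}

#' @rdname entity_token
#' @export
as_entity_ref <- function(e) {
  if (inherits(e, "entity_ref")) return(e)
  if (!is.character(e) || length(e) != 1L) {
    abort_input("expected a single 'kind:id' token")
  }
  m <- regexec("^([a-z]+):(.+)$", e)
  parts <- regmatches(e, m)[[1]]
  if (length(parts) != 3L) abort_input("malformed entity token '%s'", e)
  if (!parts[2L] %in% ENTITY_KINDS) {
    abort_input("unknown entity kind '%s' in token '%s'", parts[2L], e)
  }
  entity_ref(parts[2L], parts[3L])
}

# canonicalize a token string (lowercases gene symbols, validates ids)
canonical_token <- function(tok) entity_token(as_entity_ref(tok))

# vectorized accessors on token strings (assumed canonical)
token_kind <- function(tokens) sub("^([a-z]+):.*$", "\\1", tokens)
token_id <- function(tokens) sub("^[a-z]+:", "", tokens)

# canonical ordering of kinds for unordered pair classes
kind_rank <- function(kind) match(kind, ENTITY_KINDS)

#' Pair class of an unordered kind pair
#'
#' Co-occurrence records are classified by the unordered pair of entity
#' kinds (direction never changes the class: a gene-subject record of a
#' chemical-gene association is still class `"compound-gene"`).
#'
#' @param kind1,kind2 entity kinds.
#' @return one of `"compound-compound"`, `"compound-gene"`,
#'   `"compound-disease"`, `"gene-gene"`, `"gene-disease"`,
#'   `"disease-disease"`.
#' @examples
#' pair_class_of("disease", "compound")
#' @export
pair_class_of <- function(kind1, kind2) {
  if (!all(kind1 %in% ENTITY_KINDS) || !all(kind2 %in% ENTITY_KINDS)) {
    abort_input("unknown entity kind")
  }
  swap <- kind_rank(kind1) > kind_rank(kind2)
  a <- ifelse(swap, kind2, kind1)
  b <- ifelse(swap, kind1, kind2)
  paste0(a, "-", b)
}

PAIR_CLASSES <- c("compound-compound", "compound-gene", "compound-disease",
                  "gene-gene", "gene-disease", "disease-disease")
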