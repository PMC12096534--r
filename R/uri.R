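# characters that pass through unencoded in gene-symbol IRIs: letters,
# digits, and the five exception characters "/", "-", "_", ":", "."
IRI_SAFE_RE <- "^[A-Za-z0-9/:._-]$"

# percent-encode one symbol: every unsafe character is encoded as its
# UTF-8 octets with uppercase hex digits
pct_encode <- function(x) {
  vapply(enc2utf8(x), function(s) {
    chars <- strsplit(s, "", fixed = FALSE)[[1]]
    paste(vapply(chars, function(ch) {
      if (grepl(IRI_SAFE_RE, ch)) ch else
        paste(sprintf("%%%02X", as.integer(charToRaw(ch))), collapse = "")
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

pct_decode <- function(x) {
  vapply(x, function(s) {
    cs <- strsplit(enc2utf8(s), "", fixed = FALSE)[[1]]
    bytes <- raw(0)
    i <- 1L
    while (i <= length(cs)) {
      if (cs[i] == "%") {
        hex <- if (i + 2L <= length(cs)) paste0(cs[i + 1L], cs[i + 2L]) else ""
        if (!grepl("^[0-9A-Fa-f]{2}$", hex)) {
          abort_input("malformed percent-escape in '%s'", s)
        }
        bytes <- c(bytes, as.raw(strtoi(hex, 16L)))
        i <- i + 3L
      } else {
        bytes <- c(bytes, charToRaw(cs[i]))
        i <- i + 1L
      }
    }
    out <- rawToChar(bytes)
    Encoding(out) <- "UTF-8"
    out
  }, character(1), USE.NAMES = FALSE)
}

# IRI-local token for an entity: "CID{n}", "DZID{n}", or the encoded symbol
entity_iri_token <- function(tokens) {
  kind <- token_kind(tokens)
  id <- token_id(tokens)
  ifelse(kind == "compound", paste0("CID", id),
         ifelse(kind == "disease", paste0("DZID", id), pct_encode(id)))
}

#' Mint the IRI of a named entity
#'
#' Compounds and diseases get numeric identifiers under their subdomain
#' bases (`.../compound/CID3715`, `.../disease/DZID8173`). Gene IRIs are
#' built from the canonical lowercase gene symbol; letters, digits, and the
#' five exception characters `/`, `-`, `_`, `:`, `.` pass through and every
#' other character is percent-encoded as UTF-8 octets (uppercase hex), as
#' IRIs require.
#'
#' @param e an `entity_ref`, a token string, or a vector of tokens.
#' @param ns a [namespace_table()].
#' @return character vector of IRIs.
#' @examples
#' mint_entity_uri(entity_ref("compound", 3715))
#' mint_entity_uri(entity_ref("gene", "L(3)MBT"))
#' @export
mint_entity_uri <- function(e, ns = namespace_table()) {
  tokens <- if (inherits(e, "entity_ref")) entity_token(e) else entity_token(e)
  kind <- token_kind(tokens)
  paste0(unname(ns[kind]), entity_iri_token(tokens))
}

#' Parse an entity IRI back into an entity reference
#'
#' Inverse of [mint_entity_uri()]: recognizes the compound, disease and
#' gene namespaces, validates the `CID`/`DZID` numeric forms, and decodes
#' percent-escapes in gene symbols. Non-canonical gene IRIs (containing an
#' uppercase letter) and malformed escapes are errors.
#'
#' @param iri entity IRI.
#' @param ns a [namespace_table()].
#' @return an [entity_ref()].
#' @export
parse_entity_uri <- function(iri, ns = namespace_table()) {
  stopifnot(is.character(iri), length(iri) == 1L)
  for (kind in c("compound", "disease", "gene")) {
    base <- ns[[kind]]
    if (startsWith(iri, base)) {
      local <- substring(iri, nchar(base) + 1L)
      return(entity_from_iri_token(local, kind))
    }
  }
  abort_input("IRI '%s' is not in a known entity namespace", iri)
}

entity_from_iri_token <- function(local, kind) {
  if (kind == "compound") {
    if (!grepl("^CID[1-9][0-9]*$", local)) {
      abort_input("malformed compound IRI token '%s'", local)
    }
    entity_ref("compound", sub("^CID", "", local))
  } else if (kind == "disease") {
    if (!grepl("^DZID[1-9][0-9]*$", local)) {
      abort_input("malformed disease IRI token '%s'", local)
    }
    entity_ref("disease", sub("^DZID", "", local))
  } else {
    sym <- pct_decode(local)
    if (!identical(sym, tolower(sym))) {
      abort_input("gene IRI token '%s' is not canonical lowercase", local)
    }
    entity_ref("gene", sym)
  }
}

#' Mint the IRI of a co-occurrence node
#'
#' A reified co-occurrence statement gets a deterministic identifier built
#' from its subject and object tokens joined by `"_"`, e.g.
#' `.../cooccurrence/CID3715_DZID8173`. Direction matters: the node for
#' `A -> B` differs from the node for `B -> A`.
#'
#' @param subject,object entity refs or tokens (vectorized over tokens).
#' @param ns a [namespace_table()].
#' @return character vector of IRIs.
#' @export
mint_cooccurrence_uri <- function(subject, object, ns = namespace_table()) {
  s <- entity_token(if (inherits(subject, "entity_ref"))
    entity_token(subject) else subject)
  o <- entity_token(if (inherits(object, "entity_ref"))
    entity_token(object) else object)
  paste0(ns[["cooccurrence"]], entity_iri_token(s), "_", entity_iri_token(o))
}

#' Parse a co-occurrence node IRI
#'
#' Inverse of [mint_cooccurrence_uri()]. Because `"_"` passes through
#' unencoded in gene symbols, the local name is tokenized at the first
#' `"_"` position where both sides parse as valid entity tokens.
#'
#' @param iri co-occurrence node IRI.
#' @param ns a [namespace_table()].
#' @return `list(subject =, object =)` of [entity_ref()]s.
#' @export
parse_cooccurrence_uri <- function(iri, ns = namespace_table()) {
  base <- ns[["cooccurrence"]]
  if (!startsWith(iri, base)) {
    abort_input("IRI '%s' is not in the cooccurrence namespace", iri)
  }
  local <- substring(iri, nchar(base) + 1L)
  cuts <- gregexpr("_", local, fixed = TRUE)[[1]]
  if (cuts[1L] == -1L) abort_input("malformed co-occurrence IRI '%s'", iri)
  for (cut in cuts) {
    left <- substring(local, 1L, cut - 1L)
    right <- substring(local, cut + 1L)
    parsed <- tryCatch(
      list(subject = iri_token_to_entity(left),
           object = iri_token_to_entity(right)),
      error = function(e) NULL
    )
    if (!is.null(parsed)) return(parsed)
  }
  abort_input("malformed co-occurrence IRI '%s'", iri)
}

iri_token_to_entity <- function(local) {
  if (grepl("^CID[1-9][0-9]*$", local)) {
    entity_from_iri_token(local, "compound")
  } else if (grepl("^DZID[1-9][0-9]*$", local)) {
    entity_from_iri_token(local, "disease")
  } else {
    entity_from_iri_token(local, "gene")
  }
}
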