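#' Create a literature reference record
#'
#' One bibliographic reference (PMID-like) together with its metadata and
#' the set of named entities mentioned in its title/abstract. Mentions form
#' a set: an entity counts at most once per reference, because co-occurrence
#' is defined at document level. Year-only dates are completed to January 1
#' of that year so that date ordering is total.
#'
#' @param ref_id positive integer identifier, unique within a corpus.
#' @param title title text.
#' @param date a `Date`, an ISO-8601 `"YYYY-MM-DD"` string, or a bare
#'   `"YYYY"` year.
#' @param journal journal name.
#' @param issn optional ISSN string (`NA` for none).
#' @param authors character vector of author names.
#' @param grants list of `list(number =, agency =)` pairs; `number` may be
#'   `NA` (grantless funding acknowledgment) but `agency` must be non-empty.
#' @param mesh_headings character vector of MeSH headings.
#' @param is_review logical review-article flag.
#' @param pmc_id optional PubMedCentral id (`NA` when full text is not
#'   freely available).
#' @param mentions entity tokens (`"kind:id"`) and/or `entity_ref`s; gene
#'   symbols are canonicalized, duplicates collapse.
#' @return an object of class `reference_record`.
#' @examples
#' reference_record(1, "Indomethacin and inflammation", "2022-07-01",
#'                  "Pharm. Biol.",
#'                  mentions = c("compound:3715", "disease:8173"))
#' @export
reference_record <- function(ref_id, title, date, journal, issn = NA,
                             authors = character(), grants = list(),
                             mesh_headings = character(), is_review = FALSE,
                             pmc_id = NA, mentions = character()) {
  if (!is_count(ref_id)) abort_input("ref_id must be a positive integer")
  date <- complete_date(date)
  if (!is.character(title) || length(title) != 1L) {
    abort_input("title must be a single string")
  }
  grants <- lapply(grants, function(g) {
    g <- as.list(g)
    number <- g$number %||% NA_character_
    if (length(number) != 1L) abort_input("grant number must be scalar")
    if (!is.na(number) && !nzchar(number)) number <- NA_character_
    agency <- g$agency %||% ""
    if (!is.character(agency) || length(agency) != 1L || !nzchar(agency)) {
      abort_input("every grant entry must carry a non-empty agency")
    }
    list(number = as.character(number), agency = agency)
  })
  if (is.list(mentions)) {
    mentions <- vapply(mentions, entity_token, character(1))
  } else if (length(mentions)) {
    mentions <- entity_token(mentions)
  }
  mentions <- sort(unique(mentions))
  structure(list(
    ref_id = as.integer(ref_id), title = title, date = date,
    journal = as.character(journal), issn = as.character(issn),
    authors = as.character(authors), grants = grants,
    mesh_headings = as.character(mesh_headings),
    is_review = isTRUE(is_review),
    pmc_id = as.character(pmc_id), mentions = mentions
  ), class = "reference_record")
}

# "2015" -> 2015-01-01; otherwise ISO date
complete_date <- function(date) {
  if (inherits(date, "Date")) return(date)
  date <- as.character(date)
  if (grepl("^[0-9]{4}$", date)) date <- paste0(date, "-01-01")
  out <- as.Date(date, format = "%Y-%m-%d")
  if (is.na(out)) abort_input("unparseable date '%s'", date)
  out
}

#' @export
print.reference_record <- function(x, ...) {
  cat(sprintf("<reference_record %d: %s (%s), %d mention(s)>\n",
              x$ref_id, x$title, format(x$date), length(x$mentions)))
  invisible(x)
}

# validate a list of reference records as a corpus
validate_corpus <- function(records) {
  if (!is.list(records) || length(records) == 0L) {
    abort_input("corpus must be a non-empty list of reference records")
  }
  ok <- vapply(records, inherits, logical(1), "reference_record")
  if (!all(ok)) abort_input("corpus element %d is not a reference_record",
                            which(!ok)[1L])
  ids <- vapply(records, function(r) r$ref_id, integer(1))
  if (anyDuplicated(ids)) {
    abort_input("duplicate ref_id %d in corpus", ids[duplicated(ids)][1L])
  }
  invisible(records)
}

# long mention table: one row per (reference, entity) pair
corpus_mentions <- function(records) {
  n <- vapply(records, function(r) length(r$mentions), integer(1))
  tibble(
    ref_id = rep(vapply(records, function(r) r$ref_id, integer(1)), n),
    token = unlist(lapply(records, function(r) r$mentions),
                   use.names = FALSE) %||% character()
  )
}

#' Create an entity annotation set
#'
#' Side tables that enrich the graph beyond the mention data: preferred
#' disease labels (SKOS), species-specific gene records linking a gene
#' symbol to numbered gene ids with an organism taxon, compound role tags
#' (e.g. FDA-approved drug), and compound display names.
#'
#' @param disease_labels named character vector, names = DZIDs.
#' @param gene_records data frame with columns `gid` (positive integer,
#'   unique across all symbols), `symbol` (canonicalized), `taxon`
#'   (positive integer NCBI taxon id), `name` (preferred name).
#' @param compound_roles data frame with columns `cid`, `role`.
#' @param compound_labels named character vector, names = CIDs.
#' @return an object of class `entity_annotations`.
#' @export
entity_annotations <- function(disease_labels = character(),
                               gene_records = NULL,
                               compound_roles = NULL,
                               compound_labels = character()) {
  if (is.null(gene_records)) {
    gene_records <- tibble(gid = integer(), symbol = character(),
                           taxon = integer(), name = character())
  }
  gene_records <- as_tibble(gene_records)
  stopifnot(all(c("gid", "symbol", "taxon", "name") %in% names(gene_records)))
  if (nrow(gene_records)) {
    gene_records$symbol <- canonicalize_gene_symbol(gene_records$symbol)
    if (anyDuplicated(gene_records$gid)) {
      abort_input("gene record id %s appears under more than one entry",
                  gene_records$gid[duplicated(gene_records$gid)][1L])
    }
    if (any(gene_records$taxon < 1)) abort_input("taxon ids must be positive")
  }
  if (is.null(compound_roles)) {
    compound_roles <- tibble(cid = integer(), role = character())
  }
  compound_roles <- distinct(as_tibble(compound_roles))
  stopifnot(all(c("cid", "role") %in% names(compound_roles)))
  structure(list(
    disease_labels = disease_labels,
    gene_records = gene_records,
    compound_roles = compound_roles,
    compound_labels = compound_labels
  ), class = "entity_annotations")
}

#' @export
print.entity_annotations <- function(x, ...) {
  cat(sprintf(paste0("<entity_annotations: %d disease label(s), %d gene ",
                     "record(s), %d compound role(s), %d compound label(s)>\n"),
              length(x$disease_labels), nrow(x$gene_records),
              nrow(x$compound_roles), length(x$compound_labels)))
  invisible(x)
}
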