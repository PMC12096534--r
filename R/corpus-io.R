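CORPUS_FILE <- c(delimited = "refs.tsv", `structured-text` = "refs.yaml")

ANNOTATION_FILES <- c(disease_labels = "disease_labels.tsv",
                      gene_records = "gene_records.tsv",
                      compound_roles = "compound_roles.tsv",
                      compound_labels = "compound_labels.tsv")

#' Write a corpus (and optional annotations) to disk
#'
#' The delimited dialect is a UTF-8 tab-separated file `refs.tsv` with one
#' reference per line and eleven fields: `ref_id`, ISO-8601 `date`,
#' `journal`, `issn`, `title`, `is_review` (0/1), `pmc_id` (may be empty),
#' `authors` (";"-joined), `grants` (";"-joined `"number|agency"`, number
#' may be empty), `mesh` (";"-joined), `mentions` (";"-joined `"kind:id"`
#' tokens). The structured-text dialect stores the same records as a YAML
#' sequence in `refs.yaml`. Annotations go to sibling TSV tables
#' `disease_labels.tsv` (dzid, label), `gene_records.tsv` (gid, symbol,
#' taxon, name), `compound_roles.tsv` (cid, role) and
#' `compound_labels.tsv` (cid, label).
#'
#' @param records list of [reference_record()]s.
#' @param dir output directory (created if missing).
#' @param annotations optional [entity_annotations()].
#' @param format `"delimited"` or `"structured-text"`.
#' @return the corpus file path, invisibly.
#' @export
write_corpus <- function(records, dir, annotations = NULL,
                         format = c("delimited", "structured-text")) {
  format <- match.arg(format)
  validate_corpus(records)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, CORPUS_FILE[[format]])
  if (format == "delimited") {
    lines <- vapply(records, format_ref_line, character(1))
    writeLines(lines, path, useBytes = FALSE)
  } else {
    yaml::write_yaml(lapply(records, ref_as_list), path)
  }
  if (!is.null(annotations)) write_annotations(annotations, dir)
  invisible(path)
}

na2empty <- function(x) ifelse(is.na(x), "", x)

check_field <- function(x, what, seps = "\t") {
  pat <- paste0("[", seps, "]|[\r\n]")
  if (any(grepl(pat, x))) {
    abort_input("%s may not contain tabs, newlines or the ';' list separator",
                what)
  }
  x
}

format_ref_line <- function(r) {
  check_field(c(r$title, r$journal), "text field")
  check_field(c(r$authors, r$mesh_headings, r$mentions,
                unlist(lapply(r$grants, unlist))), "list field", "\t;")
  grants <- vapply(r$grants, function(g) {
    paste0(na2empty(g$number), "|", g$agency)
  }, character(1))
  paste(
    r$ref_id, format(r$date), r$journal, na2empty(r$issn), r$title,
    as.integer(r$is_review), na2empty(r$pmc_id),
    paste(r$authors, collapse = ";"), paste(grants, collapse = ";"),
    paste(r$mesh_headings, collapse = ";"), paste(r$mentions, collapse = ";"),
    sep = "\t"
  )
}

ref_as_list <- function(r) {
  list(ref_id = r$ref_id, date = format(r$date), journal = r$journal,
       issn = na2empty(r$issn), title = r$title, is_review = r$is_review,
       pmc_id = na2empty(r$pmc_id), authors = as.list(r$authors),
       grants = lapply(r$grants, function(g)
         list(number = na2empty(g$number), agency = g$agency)),
       mesh = as.list(r$mesh_headings), mentions = as.list(r$mentions))
}

#' Read a corpus (and annotations, when present) from disk
#'
#' Inverse of [write_corpus()]. Mention tokens are canonicalized on read
#' (gene symbols lowercased). Malformed lines, duplicate `ref_id`s and
#' unknown entity-kind tags are errors; delimited-dialect errors name the
#' offending line number.
#'
#' @param path the corpus directory, or the corpus file itself.
#' @param format `"delimited"` or `"structured-text"`.
#' @return `list(records =, annotations =)`; `annotations` is an empty
#'   [entity_annotations()] when no side tables are present.
#' @export
read_corpus <- function(path, format = c("delimited", "structured-text")) {
  format <- match.arg(format)
  if (dir.exists(path)) {
    dir <- path
    path <- file.path(dir, CORPUS_FILE[[format]])
  } else {
    dir <- dirname(path)
  }
  if (!file.exists(path)) abort_input("corpus file '%s' does not exist", path)
  records <- if (format == "delimited") {
    read_refs_delimited(path)
  } else {
    lapply(yaml::read_yaml(path), list_as_ref)
  }
  validate_corpus(records)
  list(records = records, annotations = read_annotations(dir))
}

split_list <- function(x) if (nzchar(x)) strsplit(x, ";", fixed = TRUE)[[1]] else character()

empty2na <- function(x) if (!nzchar(x)) NA_character_ else x

read_refs_delimited <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort_input("corpus file '%s' is empty", path)
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    # a trailing empty mentions field is dropped by strsplit
    if (length(fields) == 10L) fields <- c(fields, "")
    if (length(fields) != 11L) {
      abort_input("malformed corpus line %d: expected 11 fields, found %d",
                  i, length(fields))
    }
    if (!grepl("^[0-9]+$", fields[1L])) {
      abort_input("malformed corpus line %d: ref_id '%s' is not an integer",
                  i, fields[1L])
    }
    grants <- lapply(split_list(fields[9L]), function(g) {
      parts <- strsplit(g, "|", fixed = TRUE)[[1]]
      if (length(parts) == 1L) parts <- c("", parts)
      list(number = empty2na(parts[1L]),
           agency = paste(parts[-1L], collapse = "|"))
    })
    tryCatch(
      reference_record(
        ref_id = as.integer(fields[1L]), date = fields[2L],
        journal = fields[3L], issn = empty2na(fields[4L]),
        title = fields[5L], is_review = fields[6L] == "1",
        pmc_id = empty2na(fields[7L]), authors = split_list(fields[8L]),
        grants = grants, mesh_headings = split_list(fields[10L]),
        mentions = split_list(fields[11L])
      ),
      error = function(e) {
        abort_input("malformed corpus line %d: %s", i, conditionMessage(e))
      }
    )
  })
}

list_as_ref <- function(x) {
  reference_record(
    ref_id = x$ref_id, date = x$date, journal = x$journal,
    issn = empty2na(x$issn %||% ""), title = x$title,
    is_review = isTRUE(x$is_review), pmc_id = empty2na(x$pmc_id %||% ""),
    authors = unlist(x$authors) %||% character(),
    grants = lapply(x$grants, function(g)
      list(number = empty2na(g$number %||% ""), agency = g$agency)),
    mesh_headings = unlist(x$mesh) %||% character(),
    mentions = unlist(x$mentions) %||% character()
  )
}

write_annotations <- function(annotations, dir) {
  stopifnot(inherits(annotations, "entity_annotations"))
  write_tsv <- function(df, file) {
    write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tsv(data.frame(dzid = names(annotations$disease_labels),
                       label = unname(annotations$disease_labels)),
            ANNOTATION_FILES[["disease_labels"]])
  write_tsv(as.data.frame(annotations$gene_records),
            ANNOTATION_FILES[["gene_records"]])
  write_tsv(as.data.frame(annotations$compound_roles),
            ANNOTATION_FILES[["compound_roles"]])
  write_tsv(data.frame(cid = names(annotations$compound_labels),
                       label = unname(annotations$compound_labels)),
            ANNOTATION_FILES[["compound_labels"]])
  invisible(dir)
}

read_annotations <- function(dir) {
  read_tsv <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    read.delim(path, sep = "\t", colClasses = "character",
               fileEncoding = "UTF-8", check.names = FALSE)
  }
  dl <- read_tsv(ANNOTATION_FILES[["disease_labels"]])
  gr <- read_tsv(ANNOTATION_FILES[["gene_records"]])
  cr <- read_tsv(ANNOTATION_FILES[["compound_roles"]])
  cl <- read_tsv(ANNOTATION_FILES[["compound_labels"]])
  entity_annotations(
    disease_labels = if (is.null(dl) || !nrow(dl)) character() else
      setNames(dl$label, dl$dzid),
    gene_records = if (is.null(gr)) NULL else
      tibble(gid = as.integer(gr$gid), symbol = gr$symbol,
             taxon = as.integer(gr$taxon), name = gr$name),
    compound_roles = if (is.null(cr)) NULL else
      tibble(cid = as.integer(cr$cid), role = cr$role),
    compound_labels = if (is.null(cl) || !nrow(cl)) character() else
      setNames(cl$label, cl$cid)
  )
}
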