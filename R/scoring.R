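#' Scoring parameters
#'
#' Tunables of the co-occurrence scoring stage. Defaults reproduce the
#' published resource's constants: neighbor lists keep up to `K = 1000`
#' co-occurrence neighbors of each neighbor kind, and raw scores are
#' serialized to integers by multiplying by `scale = 100` and rounding to
#' the nearest integer (half away from zero).
#'
#' @param K positive integer neighbor-list cap.
#' @param scale positive integer serialization factor.
#' @param log_base base of the inverse-document-frequency logarithm.
#' @param tie_break fixed tie-break rule at the truncation boundary;
#'   currently the single rule `"score-then-iri"` (serialized score
#'   descending, then object IRI ascending).
#' @param score_fun optional replacement scoring function with signature
#'   `function(c, df_b, n, log_base)` returning the raw score; the default
#'   is the TF-IDF-variant `c * log(n / df_b, log_base)`.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(K = 1000L, scale = 100L, log_base = 10,
                           tie_break = "score-then-iri", score_fun = NULL) {
  if (!is_count(K)) abort_input("K must be a positive integer")
  if (!is_count(scale)) abort_input("scale must be a positive integer")
  if (!is.numeric(log_base) || log_base <= 0) {
    abort_input("log_base must be a positive real")
  }
  tie_break <- match.arg(tie_break, "score-then-iri")
  if (!is.null(score_fun)) stopifnot(is.function(score_fun))
  structure(list(K = as.integer(K), scale = as.integer(scale),
                 log_base = log_base, tie_break = tie_break,
                 score_fun = score_fun),
            class = "scoring_params")
}

default_raw_score <- function(c, df_b, n, log_base) {
  c * log(n / df_b, base = log_base)
}

#' Document frequencies of mentioned entities
#'
#' `df(E)` is the number of references whose mention set contains entity
#' `E`. Entities never mentioned are absent from the result.
#'
#' @param records a non-empty list of [reference_record()]s.
#' @return named integer vector keyed by entity token.
#' @export
document_frequencies <- function(records) {
  validate_corpus(records)
  m <- corpus_mentions(records)
  if (!nrow(m)) return(setNames(integer(), character()))
  tab <- table(m$token)
  setNames(as.integer(tab), names(tab))
}

#' Co-mention counts of unordered entity pairs
#'
#' `c(A, B)` is the number of references mentioning both `A` and `B`.
#' Symmetric; pairs never co-mentioned are absent.
#'
#' @inheritParams document_frequencies
#' @return tibble with columns `a`, `b` (tokens, `a < b` lexicographically)
#'   and `count`.
#' @export
comention_counts <- function(records) {
  validate_corpus(records)
  m <- corpus_mentions(records)
  if (!nrow(m)) return(tibble(a = character(), b = character(),
                              count = integer()))
  pairs <- inner_join(m, m, by = "ref_id", relationship = "many-to-many")
  pairs <- filter(pairs, .data$token.x < .data$token.y)
  out <- count(pairs, a = .data$token.x, b = .data$token.y, name = "count")
  mutate(as_tibble(out), count = as.integer(.data$count))
}

#' Co-occurrence score of a directed entity pair
#'
#' The directed score of the association `A -> B` is a TF-IDF-style
#' statistic: the number of co-mentioning documents weighted by the
#' inverse document frequency of the *object* entity,
#' `S_raw = c(A,B) * log10(N / df(B))` with the defaults. Because only the
#' object's document frequency enters, `score(A -> B) != score(B -> A)` in
#' general; that asymmetry (plus list truncation) is what makes the graph
#' directed. Serialization multiplies by `scale` (default 100) and rounds
#' to the nearest integer.
#'
#' @param c co-mention count `c(A, B)` (vectorized).
#' @param df_b document frequency of the object entity `B`.
#' @param n corpus size (number of references).
#' @param params a [scoring_params()].
#' @return `list(raw = numeric, serialized = integer)`.
#' @examples
#' cooccurrence_score(5, 10, 100)  # raw 5, serialized 500
#' @export
cooccurrence_score <- function(c, df_b, n, params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"))
  if (any(c < 1) || any(c > df_b) || any(df_b > n)) {
    abort_input(paste0("inconsistent counts: need 1 <= c <= df_b <= n ",
                       "(got c=%s, df_b=%s, n=%s)"),
                c[1L], df_b[1L], n)
  }
  fn <- params$score_fun %||% default_raw_score
  raw <- fn(c, df_b, n, params$log_base)
  list(raw = raw, serialized = as.integer(round_half_away(params$scale * raw)))
}

#' Build prioritized, truncated neighbor lists
#'
#' For every mentioned entity `A` and every neighbor kind, collects all
#' entities `B` of that kind co-mentioned with `A` at least once, scores
#' the directed association `A -> B`, sorts by raw score descending (ties
#' by object IRI ascending) and truncates to the top `K`. Truncation makes
#' neighborhood membership asymmetric: `B` in `A`'s list does not imply
#' `A` in `B`'s.
#'
#' @inheritParams document_frequencies
#' @param params a [scoring_params()].
#' @param ns a [namespace_table()] (for the tie-break IRIs).
#' @return a tibble of co-occurrence records, class `neighbor_lists`, with
#'   columns `subject`, `object` (tokens), `subject_kind`, `object_kind`,
#'   `pair_class`, `comention_count`, `raw_score`, `serialized_score`,
#'   `object_iri` and within-list `rank`; attributes `params` and `n_refs`.
#' @export
build_neighbor_lists <- function(records, params = scoring_params(),
                                 ns = namespace_table()) {
  validate_corpus(records)
  stopifnot(inherits(params, "scoring_params"))
  n <- length(records)
  df <- document_frequencies(records)
  pairs <- comention_counts(records)
  if (!nrow(pairs)) {
    out <- tibble(subject = character(), object = character(),
                  subject_kind = character(), object_kind = character(),
                  pair_class = character(), comention_count = integer(),
                  raw_score = numeric(), serialized_score = integer(),
                  object_iri = character(), rank = integer())
    return(structure(out, params = params, n_refs = n,
                     class = c("neighbor_lists", class(out))))
  }
  directed <- bind_rows(
    tibble(subject = pairs$a, object = pairs$b, comention_count = pairs$count),
    tibble(subject = pairs$b, object = pairs$a, comention_count = pairs$count)
  )
  sc <- cooccurrence_score(directed$comention_count,
                           unname(df[directed$object]), n, params)
  directed <- mutate(directed,
    subject_kind = token_kind(.data$subject),
    object_kind = token_kind(.data$object),
    pair_class = pair_class_of(.data$subject_kind, .data$object_kind),
    raw_score = sc$raw,
    serialized_score = sc$serialized,
    object_iri = mint_entity_uri(.data$object, ns = ns)
  )
  out <- directed |>
    group_by(.data$subject, .data$object_kind) |>
    arrange(dplyr::desc(.data$raw_score), dplyr::desc(.data$serialized_score),
            .data$object_iri, .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    filter(.data$rank <= params$K) |>
    ungroup() |>
    arrange(.data$subject, .data$object_kind, .data$rank) |>
    select("subject", "object", "subject_kind", "object_kind", "pair_class",
           "comention_count", "raw_score", "serialized_score", "object_iri",
           "rank")
  structure(out, params = params, n_refs = n,
            class = c("neighbor_lists", class(out)))
}

#' Extract one entity's neighbor list
#'
#' @param lists result of [build_neighbor_lists()].
#' @param anchor entity token or `entity_ref`.
#' @param kind neighbor kind.
#' @return the anchor's ordered records of that neighbor kind.
#' @export
neighbor_list <- function(lists, anchor, kind) {
  stopifnot(inherits(lists, "neighbor_lists"))
  kind <- match.arg(kind, ENTITY_KINDS)
  anchor <- entity_token(as_entity_ref(anchor))
  filter(as_tibble(lists), .data$subject == anchor, .data$object_kind == kind)
}

#' Export scored pairs as a tab-separated table
#'
#' @param lists result of [build_neighbor_lists()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scored_pairs <- function(lists, path) {
  stopifnot(inherits(lists, "neighbor_lists"))
  df <- as.data.frame(lists)[, c("subject", "object", "comention_count",
                                 "raw_score", "serialized_score")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
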