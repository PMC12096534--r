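as_token <- function(e) entity_token(as_entity_ref(e))

#' Top co-occurrence neighbors of an entity
#'
#' The knowledge-panel query: the anchor's serialized neighbors of one
#' kind, ordered by serialized co-occurrence score descending (ties by
#' neighbor IRI ascending) and truncated to `limit` (default 25, the
#' panel's display cap). Labels are joined from SKOS prefLabel where the
#' store has them. Unknown anchors yield an empty result, matching
#' SPARQL's open-world behavior.
#'
#' @param store a [load_store()] result.
#' @param anchor entity ref or token.
#' @param kind neighbor kind (`"compound"`, `"gene"`, `"disease"`).
#' @param limit maximum rows.
#' @return tibble with columns `neighbor` (token), `serialized_score`,
#'   `label` (`NA` when unlabeled).
#' @export
top_neighbors <- function(store, anchor, kind, limit = 25) {
  stopifnot(inherits(store, "cooc_store"))
  kind <- match.arg(kind, ENTITY_KINDS)
  anchor <- as_token(anchor)
  hits <- store_neighbors(store, mint_entity_uri(anchor, store$ns), kind,
                          token_kind(anchor))
  hits <- head(hits, limit)
  labels <- store_labels(store, hits$object_iri)
  tibble(
    neighbor = vapply(hits$object_iri, function(x)
      entity_token(parse_entity_uri(x, store$ns)), character(1),
      USE.NAMES = FALSE),
    serialized_score = hits$score,
    label = unname(labels[hits$object_iri])
  )
}

#' References co-mentioning a pair of entities
#'
#' Retrieves the references whose mention sets contain both entities,
#' most recent first (ties by reference id descending), optionally
#' restricted to review articles and/or to references freely available in
#' PubMedCentral.
#'
#' @param store a [load_store()] result.
#' @param a,b entity refs or tokens.
#' @param limit maximum rows.
#' @param review_only keep only review articles.
#' @param pmc_only keep only references with a PMC id.
#' @return tibble with columns `ref_id`, `date`, `journal`, `title`,
#'   `pmc_id`.
#' @export
corefs <- function(store, a, b, limit = 10, review_only = FALSE,
                   pmc_only = FALSE) {
  stopifnot(inherits(store, "cooc_store"))
  profile <- store$profile
  ns <- store$ns
  iri_a <- mint_entity_uri(as_token(a), ns)
  iri_b <- mint_entity_uri(as_token(b), ns)
  refs <- intersect(tp(store, p = profile$mention_predicate, o = iri_a)$s,
                    tp(store, p = profile$mention_predicate, o = iri_b)$s)
  if (review_only) {
    refs <- intersect(refs, tp(store, s = refs, p = rdf_type_iri(store),
                               o = profile$review_class)$s)
  }
  pmc <- tp_lit(store, s = refs, p = profile$pmc_predicate)
  if (pmc_only) refs <- intersect(refs, pmc$s)
  if (!length(refs)) {
    return(tibble(ref_id = integer(), date = as.Date(character()),
                  journal = character(), title = character(),
                  pmc_id = character()))
  }
  dates <- tp_lit(store, s = refs, p = profile$date_predicate)
  titles <- tp_lit(store, s = refs, p = profile$title_predicate)
  jlink <- tp(store, s = refs, p = profile$journal_link)
  jnames <- tp_lit(store, s = unique(jlink$o), p = profile$journal_name)
  out <- tibble(ref = refs,
                ref_id = ref_id_from_iri(refs, ns),
                date = as.Date(setNames(dates$o, dates$s)[refs]),
                title = unname(setNames(titles$o, titles$s)[refs]),
                journal = unname(setNames(jnames$o, jnames$s)[
                  setNames(jlink$o, jlink$s)[refs]]),
                pmc_id = unname(setNames(pmc$o, pmc$s)[refs]))
  out <- arrange(out, dplyr::desc(.data$date), dplyr::desc(.data$ref_id))
  head(select(out, "ref_id", "date", "journal", "title", "pmc_id"), limit)
}

#' Diseases implicitly related to a chemical via its top gene
#'
#' Finds the gene most strongly co-mentioned with the query chemical, then
#' returns that gene's top disease neighbors. Each disease is flagged by
#' whether a direct chemical-to-disease co-occurrence record also exists:
#' unflagged diseases are implicit associations reachable only through
#' the gene.
#'
#' @param store a [load_store()] result.
#' @param chemical compound ref or token.
#' @param n_diseases number of disease rows.
#' @return tibble with columns `disease` (token), `serialized_score` (of
#'   the gene-disease association), `label`, `direct` (logical).
#' @export
implicit_diseases <- function(store, chemical, n_diseases = 10) {
  stopifnot(inherits(store, "cooc_store"))
  top_gene <- top_neighbors(store, chemical, "gene", limit = 1)
  if (!nrow(top_gene)) {
    return(tibble(disease = character(), serialized_score = integer(),
                  label = character(), direct = logical()))
  }
  ds <- top_neighbors(store, top_gene$neighbor[1L], "disease",
                      limit = n_diseases)
  chem_iri <- mint_entity_uri(as_token(chemical), store$ns)
  direct_nodes <- tp(store, p = paste0(store$ns[["rdf"]], "subject"),
                     o = chem_iri)$s
  direct_objs <- tp(store, s = direct_nodes,
                    p = paste0(store$ns[["rdf"]], "object"))$o
  tibble(disease = ds$neighbor, serialized_score = ds$serialized_score,
         label = ds$label,
         direct = mint_entity_uri(ds$neighbor, store$ns) %in% direct_objs)
}

#' Chemicals co-mentioned with every gene in a set
#'
#' Gene-subject records of the chemical-gene association class are
#' intersected across the given genes; candidates may be restricted to
#' compounds bearing a role tag (e.g. `"FDAApprovedDrugs"`), and are
#' ordered by the sum of the gene-to-compound serialized scores.
#'
#' @param store a [load_store()] result.
#' @param genes gene refs or tokens (at least one).
#' @param role optional role tag (vocabulary local name) to require.
#' @param limit maximum rows.
#' @return tibble with columns `compound` (token), `label`, one score
#'   column per gene symbol, and `score_sum`.
#' @export
chemicals_for_genes <- function(store, genes, role = NULL, limit = 10) {
  stopifnot(inherits(store, "cooc_store"))
  genes <- vapply(genes, as_token, character(1), USE.NAMES = FALSE)
  if (!length(genes)) abort_input("at least one gene is required")
  per_gene <- lapply(genes, function(g) {
    hits <- store_neighbors(store, mint_entity_uri(g, store$ns), "compound",
                            "gene")
    tibble(compound_iri = hits$object_iri, score = hits$score,
           gene = token_id(g))
  })
  common <- Reduce(intersect, lapply(per_gene, function(x) x$compound_iri))
  if (!is.null(role)) {
    role_iri <- ns_expand(paste0("vocab:", role), store$ns)
    tagged <- tp(store, p = store$profile$role_predicate, o = role_iri)$s
    common <- intersect(common, tagged)
  }
  if (!length(common)) {
    out <- tibble(compound = character(), label = character())
    for (g in token_id(genes)) out[[paste0("score_", g)]] <- integer()
    out$score_sum <- integer()
    return(out)
  }
  long <- bind_rows(per_gene)
  long <- filter(long, .data$compound_iri %in% common)
  wide <- tidyr::pivot_wider(long, names_from = "gene",
                             values_from = "score", names_prefix = "score_")
  score_cols <- paste0("score_", token_id(genes))
  wide$score_sum <- as.integer(rowSums(wide[score_cols]))
  labels <- store_labels(store, wide$compound_iri)
  wide <- mutate(wide,
    compound = vapply(.data$compound_iri, function(x)
      entity_token(parse_entity_uri(x, store$ns)), character(1),
      USE.NAMES = FALSE),
    label = unname(labels[.data$compound_iri]))
  wide <- arrange(wide, dplyr::desc(.data$score_sum), .data$compound_iri)
  head(select(wide, "compound", "label", dplyr::all_of(score_cols),
              "score_sum"), limit)
}

#' Count references mentioning a compound and every gene in a set
#'
#' For each candidate compound (typically the output of
#' [chemicals_for_genes()]), counts the references whose mention set
#' contains the compound and all the genes simultaneously. Compounds with
#' no such reference are omitted; rows are count-descending.
#'
#' @param store a [load_store()] result.
#' @param compounds compound refs or tokens.
#' @param genes gene refs or tokens.
#' @return tibble with columns `compound` (token), `n_refs`.
#' @export
count_refs_mentioning_all <- function(store, compounds, genes) {
  stopifnot(inherits(store, "cooc_store"))
  compounds <- vapply(compounds, as_token, character(1), USE.NAMES = FALSE)
  genes <- vapply(genes, as_token, character(1), USE.NAMES = FALSE)
  mention <- store$profile$mention_predicate
  gene_refs <- Reduce(intersect, lapply(genes, function(g) {
    tp(store, p = mention, o = mint_entity_uri(g, store$ns))$s
  }))
  counts <- vapply(compounds, function(cmp) {
    refs <- tp(store, p = mention, o = mint_entity_uri(cmp, store$ns))$s
    length(intersect(refs, gene_refs))
  }, integer(1))
  out <- tibble(compound = compounds, n_refs = unname(counts))
  out <- filter(out, .data$n_refs > 0L)
  arrange(out, dplyr::desc(.data$n_refs), .data$compound)
}

#' Genes co-mentioned with two diseases
#'
#' The comorbidity query: the top `inner_limit` gene neighbors of the
#' first disease are intersected with the gene neighbors of the second;
#' gene names are resolved through the species-specific gene records,
#' restricted to the human taxon when `human_only` (symbols without a
#' human gene record then drop out, removing cross-species ambiguity).
#' Rows are ordered by the sum of the two serialized scores.
#'
#' @param store a [load_store()] result.
#' @param d1,d2 disease refs or tokens.
#' @param inner_limit truncation applied to `d1`'s gene list before the
#'   intersection.
#' @param human_only restrict name resolution to taxon `human_taxon`.
#' @param human_taxon NCBI taxon id treated as human.
#' @return tibble with columns `gene` (token), `name`, `score_d1`,
#'   `score_d2`, `score_sum`.
#' @export
genes_for_diseases <- function(store, d1, d2, inner_limit = 20,
                               human_only = TRUE, human_taxon = 9606) {
  stopifnot(inherits(store, "cooc_store"))
  g1 <- top_neighbors(store, d1, "gene", limit = inner_limit)
  g2 <- top_neighbors(store, d2, "gene", limit = Inf)
  merged <- inner_join(
    select(g1, gene = "neighbor", score_d1 = "serialized_score"),
    select(g2, gene = "neighbor", score_d2 = "serialized_score"),
    by = "gene")
  if (!nrow(merged)) {
    return(tibble(gene = character(), name = character(),
                  score_d1 = integer(), score_d2 = integer(),
                  score_sum = integer()))
  }
  names_df <- store_gene_names(store, merged$gene,
                               if (human_only) human_taxon else NULL)
  merged <- if (human_only) {
    inner_join(merged, names_df, by = "gene")
  } else {
    left_join(merged, names_df, by = "gene")
  }
  merged <- mutate(merged, score_sum = .data$score_d1 + .data$score_d2)
  out <- arrange(merged, dplyr::desc(.data$score_sum), .data$gene)
  select(out, "gene", "name", "score_d1", "score_d2", "score_sum")
}

# resolve gene tokens to preferred names via the numbered gene records,
# optionally restricted to one taxon; one row per resolvable token
store_gene_names <- function(store, gene_tokens, taxon = NULL) {
  ns <- store$ns
  profile <- store$profile
  sym_iri <- mint_entity_uri(gene_tokens, ns)
  links <- tp(store, p = profile$gene_symbol_pred, o = sym_iri)
  if (!is.null(taxon)) {
    keep <- tp(store, s = links$s, p = profile$organism_predicate,
               o = paste0(ns[["taxonomy"]], "TAXID", taxon))$s
    links <- links[links$s %in% keep, , drop = FALSE]
  }
  labels <- store_labels(store, links$s)
  out <- tibble(gene = token_id(gene_tokens)[match(links$o, sym_iri)],
                gid = links$s, name = unname(labels[links$s]))
  out <- mutate(out, gene = paste0("gene:", .data$gene))
  out <- arrange(out, .data$gene, .data$gid)
  distinct(select(out, "gene", "name"), .data$gene, .keep_all = TRUE)
}
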