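# Brute-force oracles: plain scans over the pre-RDF reference records,
# written independently of the package's vectorized implementations.

oracle_ns <- function() {
  c(compound = "http://rdf.ncbi.nlm.nih.gov/pubchem/compound/",
    disease = "http://rdf.ncbi.nlm.nih.gov/pubchem/disease/",
    gene = "http://rdf.ncbi.nlm.nih.gov/pubchem/gene/")
}

# generic percent-encoder with the stated exception set, byte by byte
oracle_encode <- function(sym) {
  bytes <- charToRaw(enc2utf8(sym))
  out <- vapply(as.integer(bytes), function(b) {
    ch <- rawToChar(as.raw(b))
    if (grepl("^[A-Za-z0-9]$", ch) || ch %in% c("/", "-", "_", ":", ".")) {
      ch
    } else {
      sprintf("%%%02X", b)
    }
  }, character(1))
  paste(out, collapse = "")
}

oracle_uri <- function(token) {
  kind <- sub(":.*$", "", token)
  id <- sub("^[a-z]+:", "", token)
  base <- oracle_ns()[[kind]]
  if (kind == "compound") paste0(base, "CID", id)
  else if (kind == "disease") paste0(base, "DZID", id)
  else paste0(base, oracle_encode(id))
}

oracle_df <- function(records, token) {
  sum(vapply(records, function(r) token %in% r$mentions, logical(1)))
}

oracle_comention <- function(records, a, b) {
  sum(vapply(records, function(r) {
    a %in% r$mentions && b %in% r$mentions
  }, logical(1)))
}

oracle_comention_table <- function(records) {
  counts <- list()
  for (r in records) {
    ms <- sort(r$mentions)
    if (length(ms) < 2) next
    for (i in seq_len(length(ms) - 1)) {
      for (j in seq(i + 1, length(ms))) {
        key <- paste(ms[i], ms[j], sep = "\r")
        prev <- counts[[key]]
        counts[[key]] <- (if (is.null(prev)) 0L else prev) + 1L
      }
    }
  }
  counts
}

oracle_score <- function(c, df_b, n, scale = 100, log_base = 10) {
  raw <- c * log(n / df_b, base = log_base)
  list(raw = raw, serialized = as.integer(sign(raw) * floor(abs(raw) * scale + 0.5)))
}

# all serialized neighbor records of `anchor` with objects of `kind`,
# truncated to K by (raw desc, object IRI asc), then re-ordered the way
# store queries see them: serialized desc, object IRI asc
oracle_neighbors <- function(records, anchor, kind, K = 1000L) {
  n <- length(records)
  others <- unique(unlist(lapply(records, function(r) {
    if (anchor %in% r$mentions) r$mentions else character()
  })))
  others <- setdiff(others[startsWith(others, paste0(kind, ":"))], anchor)
  if (!length(others)) {
    return(data.frame(object = character(), comention = integer(),
                      raw = numeric(), serialized = integer(),
                      uri = character(), stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, lapply(others, function(b) {
    cc <- oracle_comention(records, anchor, b)
    if (cc == 0) return(NULL)
    sc <- oracle_score(cc, oracle_df(records, b), n)
    data.frame(object = b, comention = cc, raw = sc$raw,
               serialized = sc$serialized, uri = oracle_uri(b),
               stringsAsFactors = FALSE)
  }))
  rows <- rows[order(-rows$raw, rows$uri), , drop = FALSE]
  rows <- head(rows, K)
  rows[order(-rows$serialized, rows$uri), , drop = FALSE]
}

oracle_top_neighbors <- function(records, anchor, kind, limit = 25,
                                 K = 1000L) {
  head(oracle_neighbors(records, anchor, kind, K), limit)
}

oracle_corefs <- function(records, a, b, limit = 10, review_only = FALSE,
                          pmc_only = FALSE) {
  hits <- Filter(function(r) {
    ok <- a %in% r$mentions && b %in% r$mentions
    if (review_only) ok <- ok && r$is_review
    if (pmc_only) ok <- ok && !is.na(r$pmc_id)
    ok
  }, records)
  if (!length(hits)) {
    return(data.frame(ref_id = integer(), date = as.Date(character()),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    ref_id = vapply(hits, function(r) r$ref_id, integer(1)),
    date = as.Date(vapply(hits, function(r) format(r$date), character(1))),
    journal = vapply(hits, function(r) r$journal, character(1)),
    title = vapply(hits, function(r) r$title, character(1)),
    stringsAsFactors = FALSE)
  df <- df[order(df$date, df$ref_id, decreasing = TRUE), , drop = FALSE]
  head(df, limit)
}

oracle_implicit_diseases <- function(records, chemical, n_diseases = 10,
                                     K = 1000L) {
  top_gene <- head(oracle_neighbors(records, chemical, "gene", K), 1)
  if (!nrow(top_gene)) return(data.frame(disease = character(),
                                         direct = logical()))
  ds <- head(oracle_neighbors(records, top_gene$object, "disease", K),
             n_diseases)
  direct <- vapply(ds$object, function(d) {
    oracle_comention(records, chemical, d) > 0
  }, logical(1))
  data.frame(disease = ds$object, serialized = ds$serialized,
             direct = unname(direct), stringsAsFactors = FALSE)
}

oracle_chemicals_for_genes <- function(records, genes, annotations = NULL,
                                       role = NULL, limit = 10, K = 1000L) {
  per <- lapply(genes, function(g) oracle_neighbors(records, g, "compound", K))
  common <- Reduce(intersect, lapply(per, function(x) x$object))
  if (!is.null(role) && !is.null(annotations)) {
    tagged <- paste0("compound:",
                     annotations$compound_roles$cid[
                       annotations$compound_roles$role == role])
    common <- intersect(common, tagged)
  }
  if (!length(common)) {
    return(data.frame(compound = character(), score_sum = integer()))
  }
  sums <- vapply(common, function(cmp) {
    sum(vapply(per, function(x) x$serialized[x$object == cmp], integer(1)))
  }, integer(1))
  df <- data.frame(compound = common, score_sum = unname(sums),
                   uri = vapply(common, oracle_uri, character(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$score_sum, df$uri), , drop = FALSE]
  head(df, limit)
}

oracle_count_refs_all <- function(records, compounds, genes) {
  counts <- vapply(compounds, function(cmp) {
    sum(vapply(records, function(r) {
      all(c(cmp, genes) %in% r$mentions)
    }, logical(1)))
  }, integer(1))
  df <- data.frame(compound = compounds, n_refs = unname(counts),
                   stringsAsFactors = FALSE)
  df <- df[df$n_refs > 0, , drop = FALSE]
  df[order(-df$n_refs, df$compound), , drop = FALSE]
}

oracle_genes_for_diseases <- function(records, d1, d2, annotations,
                                      inner_limit = 20, human_only = TRUE,
                                      K = 1000L) {
  g1 <- head(oracle_neighbors(records, d1, "gene", K), inner_limit)
  g2 <- oracle_neighbors(records, d2, "gene", K)
  common <- intersect(g1$object, g2$object)
  rows <- do.call(rbind, lapply(common, function(g) {
    sym <- sub("^gene:", "", g)
    recs <- annotations$gene_records[annotations$gene_records$symbol == sym, ]
    if (human_only) recs <- recs[recs$taxon == 9606L, ]
    if (human_only && !nrow(recs)) return(NULL)
    name <- if (nrow(recs)) recs$name[which.min(recs$gid)] else NA_character_
    s1 <- g1$serialized[g1$object == g]
    s2 <- g2$serialized[g2$object == g]
    data.frame(gene = g, name = name, score_d1 = s1, score_d2 = s2,
               score_sum = s1 + s2, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(gene = character(), score_sum = integer()))
  }
  rows[order(-rows$score_sum, rows$gene), , drop = FALSE]
}
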