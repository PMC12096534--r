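#' Configuration of the synthetic literature corpus generator
#'
#' The generator emulates the statistical structure the pipeline assumes
#' in real mention data: per-kind entity pools whose mention frequencies
#' follow a Zipf law, a small Poisson-distributed number of mentions per
#' reference (titles and abstracts mention few entities), planted
#' entity-pair associations enriched above the independence baseline,
#' optional planted compound-gene-set quadruples with an exact reference
#' count, and reference metadata (dates spanning many years, finite
#' journal/author/agency pools, review and PMC flags, and a configurable
#' fraction of grantless funding acknowledgments).
#'
#' @param n_refs number of references.
#' @param n_compounds,n_genes,n_diseases entity pool sizes per kind.
#' @param zipf_exponent Zipf rank-frequency exponent (> 0).
#' @param mentions_per_ref mean mentions per reference (shifted Poisson,
#'   minimum 1).
#' @param planted_pairs list of `list(a =, b =, enrichment =)` entries;
#'   `a`, `b` entity tokens, `enrichment > 1` is the target ratio of the
#'   joint co-mention probability to the realized independence baseline.
#' @param planted_quadruples list of `list(compound =, genes =, count =)`
#'   entries planted in exactly `count` references.
#' @param review_fraction,pmc_fraction,grantless_agency_fraction rates in
#'   `[0, 1]`.
#' @param seed integer RNG seed; generation is deterministic given the
#'   config.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_refs = 2000L, n_compounds = 150L,
                             n_genes = 120L, n_diseases = 100L,
                             zipf_exponent = 1.1, mentions_per_ref = 6,
                             planted_pairs = list(),
                             planted_quadruples = list(),
                             review_fraction = 0.15, pmc_fraction = 0.3,
                             grantless_agency_fraction = 0.2, seed = 1L) {
  stopifnot(is_count(n_refs), is_count(n_compounds), is_count(n_genes),
            is_count(n_diseases), zipf_exponent > 0, mentions_per_ref >= 1)
  for (f in c(review_fraction, pmc_fraction, grantless_agency_fraction)) {
    if (!is.numeric(f) || f < 0 || f > 1) {
      abort_input("fractions must lie in [0, 1]")
    }
  }
  planted_pairs <- lapply(planted_pairs, function(p) {
    p <- as.list(p)
    stopifnot(!is.null(p$a), !is.null(p$b))
    if (is.null(p$enrichment) || p$enrichment <= 1) {
      abort_input("planted pair enrichment must exceed 1")
    }
    list(a = canonical_token(p$a), b = canonical_token(p$b),
         enrichment = p$enrichment)
  })
  planted_quadruples <- lapply(planted_quadruples, function(q) {
    q <- as.list(q)
    stopifnot(!is.null(q$compound), length(q$genes) >= 1)
    if (!is_count(q$count) || q$count > n_refs) {
      abort_input("planted quadruple count must be a positive integer <= n_refs")
    }
    list(compound = canonical_token(q$compound),
         genes = vapply(q$genes, canonical_token, character(1),
                        USE.NAMES = FALSE),
         count = as.integer(q$count))
  })
  structure(list(
    n_refs = as.integer(n_refs), n_compounds = as.integer(n_compounds),
    n_genes = as.integer(n_genes), n_diseases = as.integer(n_diseases),
    zipf_exponent = zipf_exponent, mentions_per_ref = mentions_per_ref,
    planted_pairs = planted_pairs, planted_quadruples = planted_quadruples,
    review_fraction = review_fraction, pmc_fraction = pmc_fraction,
    grantless_agency_fraction = grantless_agency_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

zipf_probs <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

# entity token pools per kind; gene symbols are simple lowercase names
synthetic_pools <- function(config) {
  list(
    compound = paste0("compound:", seq_len(config$n_compounds)),
    gene = paste0("gene:g", seq_len(config$n_genes)),
    disease = paste0("disease:", seq_len(config$n_diseases))
  )
}

# per-reference marginal mention probability of the entity at `rank`
# within its kind (used to size the planted-pair mixture)
marginal_mention_prob <- function(config, kind_size, kind_share, rank) {
  p_draw <- zipf_probs(kind_size, config$zipf_exponent)[rank]
  draws <- config$mentions_per_ref * kind_share
  1 - (1 - p_draw)^draws
}

# forced-inclusion probability q so that the realized joint probability
# over realized marginals hits the requested enrichment factor E:
#   (p0 + q) = E (pA + q)(pB + q),  p0 = pA * pB
# Infeasible for very common entities: forcing the pair inflates both
# marginals, so the achievable ratio saturates below E.
plant_probability <- function(pA, pB, E) {
  p0 <- pA * pB
  a <- -E
  b <- 1 - E * (pA + pB)
  c0 <- p0 * (1 - E)
  disc <- b^2 - 4 * a * c0
  q <- if (disc >= 0) (-b + sqrt(disc)) / (2 * a) else -1
  if (q < 0 || q > 1) {
    abort_input(paste0("planted enrichment %.2f is infeasible for entities ",
                       "with marginal mention probabilities %.3f and %.3f; ",
                       "plant rarer entities or lower the factor"),
                E, pA, pB)
  }
  q
}

#' Generate a synthetic corpus
#'
#' Deterministic given the config (including its seed): the same config
#' yields byte-identical corpora. Planted quadruples appear in exactly
#' the requested number of references (accidental extra co-mentions of
#' the full quadruple are broken by removing the compound).
#'
#' @param config a [synthetic_config()].
#' @return `list(records =, annotations =)`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  pools <- synthetic_pools(config)
  sizes <- vapply(pools, length, integer(1))
  shares <- sizes / sum(sizes)
  probs <- lapply(names(pools), function(k) {
    zipf_probs(sizes[[k]], config$zipf_exponent)
  })
  names(probs) <- names(pools)
  n <- config$n_refs

  # base mention sets: kind chosen per draw by pool share, entity by Zipf
  m <- 1L + rpois(n, max(config$mentions_per_ref - 1, 0))
  mentions <- lapply(seq_len(n), function(i) {
    kinds <- sample(names(pools), m[i], replace = TRUE, prob = shares)
    unique(vapply(kinds, function(k) {
      pools[[k]][sample.int(sizes[[k]], 1L, prob = probs[[k]])]
    }, character(1), USE.NAMES = FALSE))
  })

  # planted pairs: mixture sampling -- with probability q force-include
  token_rank <- function(tok) {
    k <- token_kind(tok)
    idx <- match(tok, pools[[k]])
    if (is.na(idx)) abort_input("planted entity '%s' is outside the pool", tok)
    list(kind = k, rank = idx)
  }
  for (p in config$planted_pairs) {
    ra <- token_rank(p$a)
    rb <- token_rank(p$b)
    pA <- marginal_mention_prob(config, sizes[[ra$kind]], shares[[ra$kind]],
                                ra$rank)
    pB <- marginal_mention_prob(config, sizes[[rb$kind]], shares[[rb$kind]],
                                rb$rank)
    q <- plant_probability(pA, pB, p$enrichment)
    force_in <- runif(n) < q
    mentions[force_in] <- lapply(mentions[force_in], function(s) {
      unique(c(s, p$a, p$b))
    })
  }

  # planted quadruples: exact reference counts
  for (qd in config$planted_quadruples) {
    all_ents <- c(qd$compound, qd$genes)
    chosen <- sample.int(n, qd$count)
    mentions[chosen] <- lapply(mentions[chosen], function(s) {
      unique(c(s, all_ents))
    })
    has_all <- vapply(mentions, function(s) all(all_ents %in% s), logical(1))
    extras <- setdiff(which(has_all), chosen)
    mentions[extras] <- lapply(mentions[extras], function(s) {
      setdiff(s, qd$compound)
    })
  }

  # reference metadata from finite pools
  journals <- sprintf("J. Synth. Res. %02d", 1:20)
  issns <- sprintf("%04d-%04d", 1000 + 1:20, 2000 + 1:20)
  authors <- sprintf("Author %03d", 1:200)
  agencies <- c("National Science Agency", "Medical Research Council",
                "Health Innovation Fund", "Basic Science Foundation",
                "Translational Medicine Board", "Public Health Office")
  mesh_pool <- sprintf("Heading %02d", 1:50)
  dates <- as.Date("2010-01-01") +
    sample.int(as.integer(as.Date("2024-12-31") - as.Date("2010-01-01")) + 1L,
               n, replace = TRUE) - 1L
  is_review <- runif(n) < config$review_fraction
  has_pmc <- runif(n) < config$pmc_fraction
  grantless <- runif(n) < config$grantless_agency_fraction
  has_grant <- runif(n) < 0.5

  records <- lapply(seq_len(n), function(i) {
    j <- sample.int(length(journals), 1L)
    grants <- list()
    if (has_grant[i]) {
      grants <- list(list(
        number = sprintf("GR-%05d", sample.int(99999L, 1L)),
        agency = agencies[sample.int(length(agencies), 1L)]
      ))
    }
    if (grantless[i]) {
      grants <- c(grants, list(list(
        number = NA_character_,
        agency = agencies[sample.int(length(agencies), 1L)]
      )))
    }
    reference_record(
      ref_id = i,
      title = sprintf("Synthetic study %d on %s", i,
                      paste(head(mentions[[i]], 2L), collapse = " and ")),
      date = dates[i], journal = journals[j], issn = issns[j],
      authors = authors[sample.int(length(authors),
                                   sample.int(4L, 1L))],
      grants = grants,
      mesh_headings = mesh_pool[sample.int(length(mesh_pool),
                                           sample.int(5L, 1L))],
      is_review = is_review[i],
      pmc_id = if (has_pmc[i]) sprintf("PMC%07d", i) else NA,
      mentions = mentions[[i]]
    )
  })

  list(records = records, annotations = synthetic_annotations(config))
}

# annotations: labels for every entity, 1-3 species records per gene
# (every 7th symbol deliberately lacks a human record), roles for ~30%
# of compounds
synthetic_annotations <- function(config) {
  pools <- synthetic_pools(config)
  taxa <- c(9606L, 10090L, 7955L)  # human, mouse, zebrafish
  n_rec <- 1L + (seq_len(config$n_genes) %% 3L)
  gene_syms <- token_id(pools$gene)
  gr <- bind_rows(lapply(seq_len(config$n_genes), function(i) {
    human_less <- i %% 7L == 0L
    tx <- if (human_less) taxa[-1L][seq_len(min(n_rec[i], 2L))] else
      taxa[seq_len(n_rec[i])]
    tibble(gid = 1000L * i + seq_along(tx), symbol = gene_syms[i],
           taxon = tx,
           name = sprintf("%s protein (taxon %d)", toupper(gene_syms[i]), tx))
  }))
  fda <- seq(1L, config$n_compounds, by = 3L)
  entity_annotations(
    disease_labels = setNames(sprintf("Disease %03d", seq_len(config$n_diseases)),
                              as.character(seq_len(config$n_diseases))),
    gene_records = gr,
    compound_roles = tibble(cid = fda, role = "FDAApprovedDrugs"),
    compound_labels = setNames(sprintf("Compound %03d", seq_len(config$n_compounds)),
                               as.character(seq_len(config$n_compounds)))
  )
}
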