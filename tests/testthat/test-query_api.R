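planted_cfg <- function(n_refs, seed) {
  synthetic_config(
    n_refs = n_refs, seed = seed,
    planted_pairs = list(list(a = "compound:10", b = "disease:6",
                              enrichment = 5)))
}

make_store <- function(corpus) {
  load_store(build_bundle(corpus$records, corpus$annotations))
}

test_that("top_neighbors reproduces the serialized neighbor list", {
  corpus <- generate_corpus(planted_cfg(150, 4))
  st <- make_store(corpus)
  nl <- build_neighbor_lists(corpus$records)
  anchor <- "compound:10"
  want <- neighbor_list(nl, anchor, "disease")
  got <- top_neighbors(st, anchor, "disease", limit = Inf)
  expect_setequal(paste(got$neighbor, got$serialized_score),
                  paste(want$object, want$serialized_score))
  # scores non-increasing, labels joined from prefLabel
  expect_true(all(diff(got$serialized_score) <= 0))
  expect_true(all(got$label[got$neighbor == "disease:6"] == "Disease 006"))
  # limit semantics
  expect_identical(nrow(top_neighbors(st, anchor, "disease", limit = 3)), 3L)
  # unknown anchor: empty result, not an error
  expect_identical(nrow(top_neighbors(st, "compound:99999", "disease")), 0L)
})

test_that("a planted association ranks first for its anchor", {
  corpus <- generate_corpus(planted_cfg(800, 12))
  st <- make_store(corpus)
  top <- top_neighbors(st, "compound:10", "disease", limit = 5)
  expect_identical(top$neighbor[1L], "disease:6")
  oracle <- oracle_top_neighbors(corpus$records, "compound:10", "disease", 5)
  expect_identical(oracle$object[1L], "disease:6")
})

test_that("corefs filters and orders reference rows like the record scan", {
  corpus <- generate_corpus(planted_cfg(200, 6))
  st <- make_store(corpus)
  got <- corefs(st, "compound:10", "disease:6", limit = 10)
  want <- oracle_corefs(corpus$records, "compound:10", "disease:6", 10)
  expect_gt(nrow(want), 0L)
  expect_identical(got$ref_id, want$ref_id)
  expect_identical(got$title, want$title)
  expect_true(all(diff(as.numeric(got$date)) <= 0))
  # disjoint pair
  expect_identical(nrow(corefs(st, "compound:10", "disease:99999")), 0L)
  # review-only and pmc-only agree with the scan
  for (flags in list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
    g <- corefs(st, "compound:10", "disease:6", 50,
                review_only = flags[1], pmc_only = flags[2])
    w <- oracle_corefs(corpus$records, "compound:10", "disease:6", 50,
                       review_only = flags[1], pmc_only = flags[2])
    expect_identical(g$ref_id, w$ref_id)
    if (flags[2]) expect_true(all(!is.na(g$pmc_id)))
  }
})

test_that("implicit diseases flag direct co-mentions correctly", {
  # constructed scenario: disease:50 co-occurs with gene:g1 but never
  # with compound:70; g1 is compound:70's only (hence top) gene
  records <- list(
    ref(1, c("compound:70", "gene:g1")),
    ref(2, c("compound:70", "gene:g1")),
    ref(3, c("gene:g1", "disease:50")),
    ref(4, c("gene:g1", "disease:51")),
    ref(5, c("compound:70", "disease:51")),
    ref(6, "disease:50"))
  st <- load_store(build_bundle(records))
  got <- implicit_diseases(st, "compound:70", n_diseases = 10)
  expect_false(got$direct[got$disease == "disease:50"])
  expect_true(got$direct[got$disease == "disease:51"])
  # chemical with no gene neighbors -> empty
  st2 <- load_store(build_bundle(list(ref(1, c("compound:5", "disease:1")),
                                      ref(2, "disease:1"))))
  expect_identical(nrow(implicit_diseases(st2, "compound:5")), 0L)
})

test_that("multi-gene chemical retrieval intersects, filters roles, sums scores", {
  corpus <- generate_corpus(planted_cfg(200, 9))
  st <- make_store(corpus)
  genes <- c("gene:g1", "gene:g2", "gene:g3")
  got <- chemicals_for_genes(st, genes, limit = 10)
  want <- oracle_chemicals_for_genes(corpus$records, genes, limit = 10)
  expect_identical(got$compound, want$compound)
  expect_identical(got$score_sum, want$score_sum)
  expect_true(all(diff(got$score_sum) <= 0))
  # single gene reduces to that gene's compound neighbor ordering
  one <- chemicals_for_genes(st, "gene:g1", limit = 15)
  top <- top_neighbors(st, "gene:g1", "compound", limit = 15)
  expect_identical(one$compound, top$neighbor)
  # role restriction: FDA-approved synthetic compounds have cid %% 3 == 1
  fda <- chemicals_for_genes(st, genes, role = "FDAApprovedDrugs",
                             limit = 10)
  cids <- as.integer(sub("^compound:", "", fda$compound))
  expect_true(all(cids %% 3L == 1L))
  wfda <- oracle_chemicals_for_genes(corpus$records, genes,
                                     corpus$annotations,
                                     role = "FDAApprovedDrugs", limit = 10)
  expect_identical(fda$compound, wfda$compound)
  # a compound missing from one list is excluded
  expect_true(all(vapply(got$compound, function(cmp) {
    all(vapply(genes, function(g)
      oracle_comention(corpus$records, g, cmp) > 0, logical(1)))
  }, logical(1))))
})

test_that("simultaneous-mention counts equal the reference scan", {
  # planted quadruple in exactly 4 references
  cfg <- synthetic_config(
    n_refs = 150, seed = 15,
    planted_quadruples = list(list(compound = "compound:40",
                                   genes = c("gene:g5", "gene:g7",
                                             "gene:g11"),
                                   count = 4)))
  corpus <- generate_corpus(cfg)
  st <- make_store(corpus)
  genes <- c("gene:g5", "gene:g7", "gene:g11")
  got <- count_refs_mentioning_all(st, c("compound:40", "compound:41"),
                                   genes)
  expect_identical(got$n_refs[got$compound == "compound:40"], 4L)
  want <- oracle_count_refs_all(corpus$records,
                                c("compound:40", "compound:41"), genes)
  expect_identical(got$compound, want$compound)
  expect_identical(got$n_refs, want$n_refs)
  # a compound never co-mentioned with all genes in one paper is omitted
  expect_false("compound:41" %in% got$compound &&
                 !"compound:41" %in% want$compound)
})

test_that("comorbidity gene retrieval respects inner truncation and taxon", {
  corpus <- generate_corpus(planted_cfg(200, 18))
  st <- make_store(corpus)
  got <- genes_for_diseases(st, "disease:1", "disease:2", inner_limit = 20)
  want <- oracle_genes_for_diseases(corpus$records, "disease:1", "disease:2",
                                    corpus$annotations, inner_limit = 20)
  expect_identical(got$gene, want$gene)
  expect_identical(got$score_sum, want$score_sum)
  expect_identical(got$name, want$name)
  # human-only drops symbols with no human gene record (g7, g14, ... lack one)
  all_genes <- genes_for_diseases(st, "disease:1", "disease:2",
                                  inner_limit = 200, human_only = FALSE)
  human <- genes_for_diseases(st, "disease:1", "disease:2",
                              inner_limit = 200, human_only = TRUE)
  humanless <- paste0("gene:g", seq(7, 120, by = 7))
  expect_true(any(all_genes$gene %in% humanless))
  expect_false(any(human$gene %in% humanless))
  # a gene outside d1's top-20 is excluded even if shared
  if (nrow(all_genes) > nrow(got)) {
    expect_lt(nrow(got), nrow(all_genes))
  }
})

test_that("query operations are read-only and match oracles across seeds", {
  for (seed in c(101, 202, 303, 404)) {
    corpus <- generate_corpus(planted_cfg(120, seed))
    st <- make_store(corpus)
    size_before <- store_size(st)
    got <- top_neighbors(st, "compound:10", "disease", 25)
    want <- oracle_top_neighbors(corpus$records, "compound:10", "disease", 25)
    expect_identical(got$neighbor, want$object)
    expect_identical(got$serialized_score, want$serialized)
    gr <- corefs(st, "compound:10", "disease:6", 10)
    wr <- oracle_corefs(corpus$records, "compound:10", "disease:6", 10)
    expect_identical(gr$ref_id, wr$ref_id)
    gi <- implicit_diseases(st, "compound:10", 10)
    wi <- oracle_implicit_diseases(corpus$records, "compound:10", 10)
    expect_identical(gi$disease, wi$disease)
    expect_identical(gi$direct, wi$direct)
    expect_identical(store_size(st), size_before)
  }
})

test_that("the SPARQL templates agree with the in-package evaluation", {
  corpus <- generate_corpus(planted_cfg(150, 23))
  bundle <- build_bundle(corpus$records, corpus$annotations)
  d <- withr::local_tempdir()
  write_bundle(bundle, d, "ntriples")
  st <- load_store(bundle)
  # use case 1: identical rows in identical order
  rows <- rdflib_query(d, use_case_query("usecase1",
                                         list(cid = 10, limit = 25)))
  got <- top_neighbors(st, "compound:10", "disease", 25)
  expect_identical(
    rows,
    paste0(mint_entity_uri(got$neighbor), "\t", got$serialized_score))
  # use case 2 without a row cut: same reference set and dates
  rows2 <- rdflib_query(d, use_case_query("usecase2",
                                          list(cid = 10, dzid = 6,
                                               limit = 1000)))
  got2 <- corefs(st, "compound:10", "disease:6", limit = 1000)
  expect_identical(length(rows2), nrow(got2))
  refs <- sub("\t.*$", "", rows2)
  expect_setequal(refs, paste0(namespace_table()[["reference"]],
                               "PMID", got2$ref_id))
})

test_that("placeholder substitution is checked", {
  expect_error(use_case_query("usecase1", list(cid = 1)), "placeholder")
  expect_error(use_case_query("nope"), "unknown use-case")
  q <- use_case_query("usecase5", list(d1 = 1, d2 = 2, inner_limit = 20,
                                       taxon = 9606))
  expect_false(grepl("\\{\\{", q))
})
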