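test_that("document frequencies match direct scans", {
  records <- c(
    lapply(1:4, function(i) ref(i, c("compound:1", "disease:2"))),
    lapply(5:10, function(i) ref(i, "compound:1"))
  )
  df <- document_frequencies(records)
  expect_identical(unname(df["compound:1"]), 10L)  # saturation
  expect_identical(unname(df["disease:2"]), 4L)
  expect_false("gene:tnf" %in% names(df))
  expect_error(document_frequencies(list()), "non-empty")

  corpus <- generate_corpus(synthetic_config(n_refs = 60, seed = 11))$records
  df2 <- document_frequencies(corpus)
  for (tok in sample(names(df2), 12)) {
    expect_identical(unname(df2[tok]), oracle_df(corpus, tok))
  }
})

test_that("co-mention counts are symmetric, sparse, and match brute force", {
  records <- list(
    ref(1, c("compound:1", "disease:2", "gene:a")),
    ref(2, c("compound:1", "disease:2")),
    ref(3, c("compound:1", "gene:a")),
    ref(4, "disease:9")
  )
  cm <- comention_counts(records)
  expect_identical(cm$count[cm$a == "compound:1" & cm$b == "disease:2"], 2L)
  expect_false(any(cm$a == "disease:9" | cm$b == "disease:9"))
  expect_true(all(cm$count >= 1L))

  corpus <- generate_corpus(synthetic_config(n_refs = 80, seed = 3))$records
  cm2 <- comention_counts(corpus)
  oracle <- oracle_comention_table(corpus)
  expect_identical(nrow(cm2), length(oracle))
  for (i in sample(nrow(cm2), 25)) {
    key <- paste(cm2$a[i], cm2$b[i], sep = "\r")
    expect_identical(cm2$count[i], oracle[[key]])
  }
})

test_that("the directed score is the object-IDF TF-IDF variant", {
  s <- cooccurrence_score(5, 10, 100)
  expect_equal(s$raw, 5)
  expect_identical(s$serialized, 500L)
  # df equal to corpus size: log(1) = 0
  s0 <- cooccurrence_score(3, 100, 100)
  expect_equal(s0$raw, 0)
  expect_identical(s0$serialized, 0L)
  # direction matters: score(A->B) uses df(B) only
  ab <- cooccurrence_score(4, 10, 1000)
  ba <- cooccurrence_score(4, 400, 1000)
  expect_gt(ab$raw, ba$raw)
  expect_error(cooccurrence_score(11, 10, 100), "inconsistent counts")
  expect_error(cooccurrence_score(5, 101, 100), "inconsistent counts")
})

test_that("raw scores are monotone in count and antitone in object df", {
  n <- 500
  for (df_b in c(2, 17, 130)) {
    raws <- cooccurrence_score(1:df_b, df_b, n)$raw
    expect_true(all(diff(raws) > 0))
  }
  for (cc in c(1, 5, 20)) {
    raws <- vapply(seq(cc, 400, by = 7), function(d)
      cooccurrence_score(cc, d, n)$raw, numeric(1))
    expect_true(all(diff(raws) < 0))
  }
})

test_that("serialization is the scale-and-round of the raw score", {
  corpus <- generate_corpus(synthetic_config(n_refs = 120, seed = 5))$records
  nl <- build_neighbor_lists(corpus)
  expect_true(all(nl$serialized_score >= 0L))
  expect_true(all(nl$serialized_score == floor(abs(nl$raw_score) * 100 + 0.5)))
  # independent recomputation from counts
  n <- length(corpus)
  for (i in sample(nrow(nl), 20)) {
    o <- oracle_score(nl$comention_count[i],
                      oracle_df(corpus, nl$object[i]), n)
    expect_equal(nl$raw_score[i], o$raw)
    expect_identical(nl$serialized_score[i], o$serialized)
  }
})

test_that("neighbor lists cap at K, sort by score, and stay consistent", {
  corpus <- fanout_corpus(40)
  nl <- build_neighbor_lists(corpus, scoring_params(K = 25))
  dz <- neighbor_list(nl, "compound:1", "disease")
  expect_identical(nrow(dz), 25L)
  expect_true(all(diff(dz$raw_score) <= 0))
  # below the cap the list is complete
  anchor3 <- list(ref(1, c("compound:9", "disease:1")),
                  ref(2, c("compound:9", "disease:2")),
                  ref(3, c("compound:9", "disease:3")),
                  ref(4, "disease:1"))
  nl3 <- build_neighbor_lists(anchor3)
  expect_identical(nrow(neighbor_list(nl3, "compound:9", "disease")), 3L)
  # every entry shares the anchor and the neighbor kind
  expect_true(all(dz$subject == "compound:1"))
  expect_true(all(dz$object_kind == "disease"))
})

test_that("truncation makes neighborhood membership asymmetric", {
  records <- asymmetric_corpus()
  params <- scoring_params(K = 10)
  nl <- build_neighbor_lists(records, params)
  a_list <- neighbor_list(nl, "compound:1", "disease")
  b_list <- neighbor_list(nl, "disease:1", "compound")
  expect_true("disease:1" %in% a_list$object)
  expect_false("compound:1" %in% b_list$object)
  # brute-force confirmation
  ob <- oracle_neighbors(records, "disease:1", "compound", K = 10)
  expect_false("compound:1" %in% ob$object)
  oa <- oracle_neighbors(records, "compound:1", "disease", K = 10)
  expect_true("disease:1" %in% oa$object)
})

test_that("full scoring pipeline equals the brute-force oracle on small corpora", {
  for (seed in c(2, 19, 301)) {
    corpus <- generate_corpus(synthetic_config(n_refs = 90, seed = seed))$records
    nl <- build_neighbor_lists(corpus)
    anchors <- unique(nl$subject)
    for (anchor in sample(anchors, 6)) {
      for (kind in c("compound", "gene", "disease")) {
        got <- neighbor_list(nl, anchor, kind)
        want <- oracle_neighbors(corpus, anchor, kind)
        expect_setequal(paste(got$object, got$serialized_score),
                        paste(want$object, want$serialized))
      }
    }
  }
})

test_that("scored-pairs export writes the documented five columns", {
  corpus <- fanout_corpus(4)
  nl <- build_neighbor_lists(corpus)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scored_pairs(nl, f)
  back <- read.delim(f)
  expect_identical(names(back), c("subject", "object", "comention_count",
                                  "raw_score", "serialized_score"))
  expect_identical(nrow(back), nrow(nl))
})
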