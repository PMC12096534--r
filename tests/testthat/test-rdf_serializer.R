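mini_lists <- function(n_diseases = 7) {
  build_neighbor_lists(fanout_corpus(n_diseases))
}

test_that("each co-occurrence record serializes to exactly five triples", {
  nl <- mini_lists(7)
  cd <- nl[nl$pair_class == "compound-disease" &
             nl$subject == "compound:1", ]
  tr <- serialize_cooccurrences(cd, predicate_profile())
  expect_identical(nrow(tr), 5L * nrow(cd))
  # typed with the chemical-disease association class
  expect_true(all(
    paste0(namespace_table()[["sio"]], "SIO_000993") %in%
      tr$o[tr$p == paste0(namespace_table()[["rdf"]], "type")]))
  # empty input gives the empty graph
  expect_identical(nrow(serialize_cooccurrences(nl[0, ])), 0L)
  # scores are integer-typed literals
  score_rows <- tr[tr$p == predicate_profile()$score_predicate, ]
  expect_true(all(score_rows$lit))
  expect_true(all(score_rows$dtype ==
                    "http://www.w3.org/2001/XMLSchema#integer"))
  expect_true(all(grepl("^[0-9]+$", score_rows$o)))
})

test_that("a missing pair-class mapping is an error naming the class", {
  nl <- mini_lists(3)
  profile <- predicate_profile()
  profile$association_classes <-
    profile$association_classes[c("compound-gene", "gene-disease")]
  expect_error(serialize_cooccurrences(nl, profile), "compound-disease")
})

test_that("reference serialization covers mentions, metadata, and funding", {
  profile <- predicate_profile()
  ns <- namespace_table()
  records <- list(
    reference_record(1, "Two mentions", "2020-05-01", "J. A",
                     mentions = c("compound:3715", "disease:8173")),
    reference_record(2, "Grantless", "2019-01-01", "J. A",
                     grants = list(list(number = NA, agency = "Agency X"))),
    reference_record(3, "Granted", "2018-01-01", "J. B", issn = "9999-0000",
                     authors = "A One",
                     grants = list(list(number = "G-77", agency = "Agency X")),
                     mesh_headings = "Heading", is_review = TRUE,
                     pmc_id = "PMC9")
  )
  tr <- serialize_references(records, profile, ns)
  ref1 <- paste0(ns[["reference"]], "PMID1")
  mention <- tr[tr$s == ref1 & tr$p == profile$mention_predicate, ]
  expect_identical(nrow(mention), 2L)
  expect_setequal(mention$o, c(paste0(ns[["compound"]], "CID3715"),
                               paste0(ns[["disease"]], "DZID8173")))
  # grantless acknowledgment: direct reference->agency link, no grant node
  ref2 <- paste0(ns[["reference"]], "PMID2")
  expect_identical(nrow(tr[tr$s == ref2 & tr$p == profile$agency_link, ]), 1L)
  expect_identical(nrow(tr[tr$s == ref2 & tr$p == profile$grant_link, ]), 0L)
  # numbered grant: indirect route through the grant node
  ref3 <- paste0(ns[["reference"]], "PMID3")
  grant_nodes <- tr$o[tr$s == ref3 & tr$p == profile$grant_link]
  expect_length(grant_nodes, 1L)
  expect_identical(tr$o[tr$s == grant_nodes & tr$p == profile$grant_number],
                   "G-77")
  expect_identical(nrow(tr[tr$s == grant_nodes &
                             tr$p == profile$agency_link, ]), 1L)
  # review class and PMC availability
  expect_true(profile$review_class %in%
                tr$o[tr$s == ref3 & tr$p == paste0(ns[["rdf"]], "type")])
  expect_identical(tr$o[tr$s == ref3 & tr$p == profile$pmc_predicate], "PMC9")
  # a mention-less reference still carries metadata
  expect_identical(nrow(tr[tr$s == ref2 &
                             tr$p == profile$mention_predicate, ]), 0L)
  expect_identical(nrow(tr[tr$s == ref2 & tr$p == profile$title_predicate, ]),
                   1L)
})

test_that("entity annotations serialize labels, roles, and gene records", {
  profile <- predicate_profile()
  ns <- namespace_table()
  ann <- entity_annotations(
    disease_labels = c("8173" = "Inflammation"),
    gene_records = data.frame(gid = 672L, symbol = "brca1", taxon = 9606L,
                              name = "Breast cancer 1"),
    compound_roles = data.frame(cid = 3715L, role = "FDAApprovedDrugs"))
  tr <- serialize_entities(ann, profile, ns)
  expect_identical(
    tr$o[tr$s == paste0(ns[["disease"]], "DZID8173") &
           tr$p == profile$pref_label],
    "Inflammation")
  gid <- paste0(ns[["gene"]], "GID672")
  expect_identical(tr$o[tr$s == gid & tr$p == profile$gene_symbol_pred],
                   paste0(ns[["gene"]], "brca1"))
  expect_identical(tr$o[tr$s == gid & tr$p == profile$organism_predicate],
                   paste0(ns[["taxonomy"]], "TAXID9606"))
  expect_identical(
    tr$o[tr$s == paste0(ns[["compound"]], "CID3715") &
           tr$p == profile$role_predicate],
    paste0(ns[["vocab"]], "FDAApprovedDrugs"))
})

test_that("bundles partition triples by subject subdomain, exactly once", {
  corpus <- generate_corpus(synthetic_config(n_refs = 60, seed = 2))
  bundle <- build_bundle(corpus$records, corpus$annotations)
  ns <- namespace_table()
  bases <- ns[c("cooccurrence", "reference", "compound", "gene", "disease",
                "journal", "author", "grant", "organization")]
  total <- 0L
  for (nm in names(bases)) {
    tr <- bundle[[nm]]
    total <- total + nrow(tr)
    expect_true(all(startsWith(tr$s, bases[[nm]])), info = nm)
  }
  expect_identical(total, nrow(coocrdf:::bundle_triples(bundle)))
  # co-occurrence subjects all parse back to their entity pair
  cooc <- bundle$cooccurrence
  some <- sample(unique(cooc$s), 10)
  for (s in some) {
    expect_silent(parse_cooccurrence_uri(s))
  }
  expect_error(graph_bundle(coocrdf:::triple_iri("http://example.org/x",
                                                 "http://example.org/p",
                                                 "http://example.org/y")),
               "no known subdomain")
})

test_that("write/read round-trips bundles exactly in both formats", {
  corpus <- generate_corpus(synthetic_config(n_refs = 50, seed = 9))
  bundle <- build_bundle(corpus$records, corpus$annotations)
  want <- coocrdf:::bundle_triples(bundle)
  for (fmt in c("turtle", "ntriples")) {
    d <- withr::local_tempdir()
    files <- write_bundle(bundle, d, fmt)
    expect_true(length(files) >= 2L)
    expect_true(all(dir.exists(file.path(d, c("cooccurrence", "reference")))))
    back <- read_bundle(d)
    expect_true(coocrdf:::same_triple_set(want,
                                          coocrdf:::bundle_triples(back)))
  }
})

test_that("serialization is deterministic: same input, identical bytes", {
  corpus <- generate_corpus(synthetic_config(n_refs = 40, seed = 13))
  b1 <- build_bundle(corpus$records, corpus$annotations)
  b2 <- build_bundle(corpus$records, corpus$annotations)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b1, d1, "ntriples")
  write_bundle(b2, d2, "ntriples")
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})

test_that("emitted files parse under an independent third-party parser", {
  corpus <- generate_corpus(synthetic_config(n_refs = 40, seed = 21))
  bundle <- build_bundle(corpus$records, corpus$annotations)
  formats <- c(ntriples = "nt", turtle = "turtle")
  for (fmt in names(formats)) {
    d <- withr::local_tempdir()
    files <- write_bundle(bundle, d, fmt)
    for (f in files) {
      ours <- if (fmt == "ntriples") parse_ntriples(f) else parse_turtle(f)
      expect_identical(rdflib_count(f, formats[[fmt]]), nrow(ours), info = f)
    }
  }
})

test_that("literal escaping survives the N-Triples round trip", {
  tricky <- 'He said "x\\y"\tthen\nleft. '
  tr <- coocrdf:::triple_lit(
    "http://rdf.ncbi.nlm.nih.gov/pubchem/reference/PMID1",
    "http://purl.org/dc/terms/title", tricky)
  f <- withr::local_tempfile(fileext = ".nt")
  write_ntriples(tr, f)
  back <- parse_ntriples(f)
  expect_identical(back$o, tricky)
})
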