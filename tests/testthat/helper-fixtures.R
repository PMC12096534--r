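# deterministic hand-built corpora and small utilities shared by tests

ref <- function(id, mentions, date = "2020-01-01", journal = "J. Test",
                ...) {
  reference_record(ref_id = id, title = paste("Study", id), date = date,
                   journal = journal, mentions = mentions, ...)
}

# corpus where one compound anchor co-occurs with `n_diseases` distinct
# diseases, one reference per pair
fanout_corpus <- function(n_diseases, anchor = "compound:1") {
  lapply(seq_len(n_diseases), function(i) {
    ref(i, c(anchor, paste0("disease:", i)))
  })
}

# rare anchor A + ubiquitous neighbor B: B makes A's (short) neighbor
# list, while A is pushed out of B's truncated list by stronger neighbors
asymmetric_corpus <- function(n_strong = 15, refs_per_strong = 10,
                              filler = 120) {
  records <- list()
  id <- 0L
  nxt <- function() {
    id <<- id + 1L
    id
  }
  # strong compound neighbors of disease:1, each co-mentioned often
  for (k in seq_len(n_strong)) {
    for (j in seq_len(refs_per_strong)) {
      records[[length(records) + 1L]] <-
        ref(nxt(), c(paste0("compound:", k + 100), "disease:1"))
    }
    # extra solo mentions raise each strong compound's df moderately
    for (j in seq_len(5)) {
      records[[length(records) + 1L]] <-
        ref(nxt(), paste0("compound:", k + 100))
    }
  }
  # the rare anchor compound:1 appears exactly once, with disease:1
  records[[length(records) + 1L]] <- ref(nxt(), c("compound:1", "disease:1"))
  # filler references mentioning disease:1 alone (raise its df)
  for (j in seq_len(filler)) {
    records[[length(records) + 1L]] <- ref(nxt(), "disease:1")
  }
  records
}

has_python_rdflib <- local({
  status <- NULL
  function() {
    if (is.null(status)) {
      status <<- suppressWarnings(
        system2("python", c("-c", "import rdflib"),
                stdout = FALSE, stderr = FALSE)) == 0
    }
    status
  }
})

# run a SPARQL query over the N-Triples files below `dir` with rdflib,
# returning one tab-joined line per result row
rdflib_query <- function(dir, query) {
  qfile <- tempfile(fileext = ".rq")
  writeLines(query, qfile)
  py <- sprintf('
import glob, rdflib
g = rdflib.Graph()
for f in glob.glob(%s + "/**/*.nt", recursive=True):
    g.parse(f, format="nt")
for row in g.query(open(%s).read()):
    print("\\t".join("" if v is None else str(v) for v in row))
', deparse(dir), deparse(qfile))
  system2("python", c("-c", shQuote(py)), stdout = TRUE)
}

rdflib_count <- function(path, format) {
  py <- sprintf('
import rdflib
g = rdflib.Graph()
g.parse(%s, format=%s)
print(len(g))
', deparse(path), deparse(format))
  as.integer(system2("python", c("-c", shQuote(py)), stdout = TRUE))
}
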