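#' SPARQL 1.1 texts of the use-case queries
#'
#' The five literature-mining use cases ship as SPARQL text assets with
#' `{{placeholder}}` parameters (under `inst/sparql/`), so the same
#' questions can be posed to any external SPARQL 1.1 engine hosting the
#' written bundle. In-package, the equivalent operations
#' ([top_neighbors()], [corefs()], [implicit_diseases()],
#' [chemicals_for_genes()], [count_refs_mentioning_all()],
#' [genes_for_diseases()]) evaluate the same graph patterns against the
#' loaded store.
#'
#' @param name asset name: one of `"usecase1"`, `"usecase2"`,
#'   `"usecase3"`, `"usecase4"`, `"usecase4_counts"`, `"usecase5"`.
#' @param params named list substituted into `{{...}}` placeholders.
#' @return the query text (single string).
#' @examples
#' cat(use_case_query("usecase1", list(cid = 3715, limit = 25)))
#' @export
use_case_query <- function(name, params = list()) {
  path <- system.file("sparql", paste0(name, ".rq"), package = "coocrdf")
  if (!nzchar(path)) abort_input("unknown use-case query '%s'", name)
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  for (key in names(params)) {
    txt <- gsub(paste0("{{", key, "}}"), as.character(params[[key]]),
                txt, fixed = TRUE)
  }
  left <- regmatches(txt, gregexpr("\\{\\{[a-z0-9_]+\\}\\}", txt))[[1]]
  if (length(left)) {
    abort_input("missing value for query placeholder %s", left[1L])
  }
  txt
}
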