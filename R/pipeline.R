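PIPELINE_DEFAULTS <- list(
  input = NA_character_, output = NA_character_,
  format = "ntriples", k = 1000L, scale = 100L, log_base = 10,
  limit = 25L, corefs_limit = 10L, inner_limit = 20L, seed = 1L,
  n_refs = 2000L, n_compounds = 150L, n_genes = 120L, n_diseases = 100L,
  zipf_exponent = 1.1, mentions_per_ref = 6,
  review_fraction = 0.15, pmc_fraction = 0.3,
  grantless_agency_fraction = 0.2
)

#' Read a flat key-value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys
#' are rejected. Defaults reproduce the model's published constants
#' (`k = 1000` neighbor cap, `scale = 100` serialization factor, result
#' limits 25/10/20).
#'
#' @param path config file; `NULL` yields pure defaults.
#' @return named list of pipeline settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- PIPELINE_DEFAULTS
  if (is.null(path)) return(cfg)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    m <- regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3L) abort_input("bad config line '%s'", ln)
    key <- parts[2L]
    if (!key %in% names(cfg)) abort_input("unknown config key '%s'", key)
    old <- cfg[[key]]
    cfg[[key]] <- if (is.numeric(old) || all(is.na(old))) {
      if (grepl("^-?[0-9.]+$", parts[3L])) as.numeric(parts[3L]) else parts[3L]
    } else {
      parts[3L]
    }
  }
  for (key in c("k", "scale", "limit", "corefs_limit", "inner_limit",
                "seed", "n_refs", "n_compounds", "n_genes", "n_diseases")) {
    cfg[[key]] <- as.integer(cfg[[key]])
  }
  cfg
}

config_scoring_params <- function(cfg) {
  scoring_params(K = cfg$k, scale = cfg$scale, log_base = cfg$log_base)
}

config_synthetic <- function(cfg, planted_pairs = list(),
                             planted_quadruples = list()) {
  synthetic_config(
    n_refs = cfg$n_refs, n_compounds = cfg$n_compounds,
    n_genes = cfg$n_genes, n_diseases = cfg$n_diseases,
    zipf_exponent = cfg$zipf_exponent,
    mentions_per_ref = cfg$mentions_per_ref,
    planted_pairs = planted_pairs,
    planted_quadruples = planted_quadruples,
    review_fraction = cfg$review_fraction, pmc_fraction = cfg$pmc_fraction,
    grantless_agency_fraction = cfg$grantless_agency_fraction,
    seed = cfg$seed)
}
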