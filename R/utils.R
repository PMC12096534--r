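`%||%` <- function(x, y) if (is.null(x)) y else x

# round half away from zero (scores are non-negative, but keep the general form)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

abort_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# evaluate `code` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == as.integer(x)
}
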