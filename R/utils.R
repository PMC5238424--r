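# Internal helpers shared across the pipeline.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage substream: a master seed plus a stage name yields a
# stable 31-bit seed, so toggling one stage never shifts another stage's draws.
substream_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  codes <- as.numeric(utf8ToInt(stream))
  h <- sum(codes * seq_along(codes) * 2654435)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Taxon-name normalization used everywhere names are matched: trim whitespace,
# collapse internal whitespace to a single underscore. Exact match after that;
# no fuzzy matching.
normalize_taxon <- function(x) {
  x <- trimws(x)
  gsub("[[:space:]]+", "_", x)
}

frobenius <- function(m) sqrt(sum(m^2))

# Permutation p-value with the add-one rule (never exactly zero).
perm_pvalue <- function(null_stats, observed, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  hits <- if (tail == "ge") sum(null_stats >= observed) else sum(null_stats <= observed)
  (hits + 1) / (length(null_stats) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_mr <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)
warn_mr <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)
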