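# Internal helpers: typed conditions and local RNG scoping.

# Typed errors so callers (and the CLI) can map failure modes to exit codes.
gh_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "genehood_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

gh_schema_error    <- function(msg, ...) gh_error("genehood_schema_error", msg, ...)
gh_integrity_error <- function(msg, ...) gh_error("genehood_integrity_error", msg, ...)
gh_parameter_error <- function(msg, ...) gh_error("genehood_parameter_error", msg, ...)
gh_empty_error     <- function(msg, ...) gh_error("genehood_empty_error", msg, ...)

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    gh_parameter_error("`seed` must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

TAXON_RANKS <- c("phylum", "class", "order", "family", "genus")

check_rank <- function(rank) {
  if (!is.character(rank) || length(rank) != 1L || !rank %in% TAXON_RANKS) {
    gh_parameter_error(sprintf(
      "`rank` must be one of: %s", paste(TAXON_RANKS, collapse = ", ")
    ))
  }
  rank
}
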