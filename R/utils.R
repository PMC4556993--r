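# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific seed from a global seed by stable string hashing,
# so each pipeline stage is reproducible independently of execution order.
stageSeed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1048573L
  as.integer((as.integer(seed) %% 1048573L) * 1021L + h) %% 2147483647L
}

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

randomDna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Copy-weighted mode; ties broken toward the smallest value.
weightedMode <- function(values, weights) {
  if (length(values) == 0L) return(NA_integer_)
  tab <- tapply(weights, values, sum)
  keys <- as.numeric(names(tab))
  keys[order(-as.numeric(tab), keys)][1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

asScaffoldSet <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (!is(x, "DNAStringSet")) stop("genome must be a named DNAStringSet")
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("scaffold names must be present and unique")
  x
}
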