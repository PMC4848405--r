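#' @keywords internal
"_PACKAGE"

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index; stays below 2^31.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  # double arithmetic: the product stays below 2^53, the result below 2^31
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9973) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
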