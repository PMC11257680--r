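# Seed derivation and scoped RNG helpers.
#
# Every stochastic component draws from a named stream derived from the
# user-facing seed, so that e.g. the environment stream is identical between a
# gated run and its parallel control.

#' Derive a reproducible integer sub-seed from a base seed and a stream name
#'
#' @param seed integer base seed.
#' @param stream character stream name (e.g. "environment", "stm").
#' @param index optional integer index for families of streams.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @keywords internal
derive_seed <- function(seed, stream = "default", index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- (abs(seed) %% 2147483647)
  for (ch in utf8ToInt(as.character(stream))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h <- (h * 31 + abs(index) * 2654435761) %% 2147483647
  as.integer(h %% 2147483646L + 1L)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code does not perturb the
#' caller's RNG state. A `NULL` seed evaluates the expression as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
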