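#' Evaluate an expression under a temporary RNG state
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the previous global
#' RNG state so that callers' random streams are unaffected. All stochastic
#' generators in the package route their randomness through this helper, which
#' makes every output a pure function of (arguments, seed).
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a base seed and a stream label
#'
#' Deterministic, collision-poor mapping used to give independent substreams
#' (per subject, channel, stage) their own seeds while keeping everything a
#' function of the top-level seed. Result is kept within 32-bit integer range.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return integer scalar.
#' @keywords internal
child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
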