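#' Evaluate an expression with a temporary RNG seed
#'
#' All stochastic operations in the package funnel their `seed` argument
#' through this helper so that the caller's RNG stream is left untouched and
#' results are reproducible. A `NULL` seed uses (and advances) the current
#' RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
local_seed_eval <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed from a parent seed
#'
#' Deterministic mixing keeps per-stage seeds distinct while staying inside
#' the 32-bit integer range.
#'
#' @param seed Parent integer seed.
#' @param k Stage index (small integer).
#' @return Integer seed.
#' @keywords internal
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}
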