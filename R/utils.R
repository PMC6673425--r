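# Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG
#' state, so seeded package functions never perturb the user's random
#' stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise a stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Deterministic per-feature sub-seed
#'
#' Maps (master seed, gene, panel) to an integer below 2^31 so permutation
#' results do not depend on scan order or parallel chunking. Uses a small
#' multiplicative string hash; collisions are harmless (features are still
#' permuted independently, just from the same stream start).
#'
#' @keywords internal
#' @noRd
feature_seed <- function(seed, gene, panel) {
  key <- paste0(gene, "\r", panel)
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 1000000007
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

# stopifnot-style check with a readable message
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
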