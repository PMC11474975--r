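##
## Internal helpers: seeded RNG scopes and small numeric utilities.
##

#' Evaluate an expression under a local RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so package functions never leak RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a substream seed from (seed, index) staying below 2^31.
## Simple multiplicative mix; collisions irrelevant at fixture scale.
subseed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807 + 11) %% 2147483629
  as.integer(s)
}

## Euclidean norms of the rows of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pd <- function(...) stop(sprintf(...), call. = FALSE)

warn_pd <- function(...) warning(sprintf(...), call. = FALSE)
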