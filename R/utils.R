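## Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded simulators do not
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

## coerce any Matrix/base matrix to a base dense matrix
as_dense <- function(x) {
  if (is(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

## row-normalize a nonnegative matrix; zero rows left at zero
row_normalize <- function(x) {
  rs <- rowSums(x)
  rs[rs == 0] <- 1
  x / rs
}

is_count_like <- function(x, tol = 1e-8) {
  v <- if (is(x, "sparseMatrix")) x@x else as.numeric(x)
  length(v) == 0L || (all(v >= 0) && all(abs(v - round(v)) < tol))
}
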