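## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded simulations do not perturb surrounding randomness.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Cache for permutation matrices used by exact rank-permutation inference.
.perm_cache <- new.env(parent = emptyenv())

#' All permutations of 1..n as a matrix
#'
#' Rows are the n! permutations, built recursively and cached per n.
#' Used for exact permutation null distributions at small n.
#'
#' @param n Number of elements (kept small; n! rows are materialized).
#' @return Integer matrix with n! rows and n columns.
#' @keywords internal
permutation_matrix <- function(n) {
  stopifnot(n >= 1, n <= 9)
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  build <- function(k) {
    if (k == 1L) return(matrix(1L, 1L, 1L))
    sub <- build(k - 1L)
    blocks <- lapply(seq_len(k), function(v) {
      m <- sub
      m[m >= v] <- m[m >= v] + 1L
      cbind(rep(v, nrow(m)), m, deparse.level = 0)
    })
    do.call(rbind, blocks)
  }
  out <- build(as.integer(n))
  .perm_cache[[key]] <- out
  out
}

## Stop with a classed condition so callers/tests can match on error type.
stop_mirscreen <- function(msg, class) {
  stop(structure(
    class = c(class, "mirscreen_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
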