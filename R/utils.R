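# Internal numeric and RNG helpers shared across the package.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded package
#' internals never perturb user-level random number streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Numerically stable log(sum(exp(x))) for a vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise logsumexp of a matrix, returning a vector (one per column).
col_logsumexp <- function(M) {
  m <- M[cbind(max.col(t(M), ties.method = "first"), seq_len(ncol(M)))]
  m + log(colSums(exp(M - rep(m, each = nrow(M)))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Column-wise argmax with lowest-index tie-breaking.
col_argmax <- function(M) max.col(t(M), ties.method = "first")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
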