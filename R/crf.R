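# Linear-chain CRF over emission scores: path scoring, exact log-partition
# via the forward recursion, log-likelihood, marginals for gradients,
# Viterbi decoding, and the independent per-token softmax ablation.
#
# Conventions: the emission matrix F is K x T (F[i, t] scores tag i at
# position t). The transition matrix A is (K+1) x (K+1): rows/columns
# 1..K are tags, row K+1 is the START state and column K+1 the STOP
# state, so A[START, k] scores starting in tag k and A[j, STOP] scores
# ending in tag j. All computations are carried out in log space.

check_emissions <- function(F_mat) {
  if (!is.matrix(F_mat) || ncol(F_mat) < 1L) {
    stop_config("emission matrix must have at least one column (T >= 1)")
  }
  if (!all(is.finite(F_mat))) stop_config("emission scores must be finite")
}

#' Score a tag path through a sentence
#'
#' Computes the path score
#' `S = sum_t (A[y[t-1], y[t]] + F[y[t], t])` with `y[0] = START`, plus
#' the terminal transition `A[y[T], STOP]`.
#'
#' @param F_mat `K x T` emission score matrix.
#' @param A `(K+1) x (K+1)` transition matrix (START row, STOP column).
#' @param y integer tag-index path of length `T` (values in `1..K`).
#' @return the path score (a scalar).
#' @export
sentence_score <- function(F_mat, A, y) {
  check_emissions(F_mat)
  K <- nrow(F_mat); Tn <- ncol(F_mat)
  if (length(y) != Tn) {
    stop_config("path length %d does not match T = %d", length(y), Tn)
  }
  if (any(y < 1L | y > K)) stop_config("tag indices must lie in 1..%d", K)
  START <- K + 1L; STOP <- K + 1L
  prev <- c(START, y[-Tn])
  sum(A[cbind(prev, y)]) + sum(F_mat[cbind(y, seq_len(Tn))]) + A[y[Tn], STOP]
}

# Forward recursion in log space; returns the K x T matrix of log alpha
# values (alpha[k, t] = log-sum over paths ending in tag k at t).
crf_forward <- function(F_mat, A) {
  K <- nrow(F_mat); Tn <- ncol(F_mat); START <- K + 1L
  alpha <- matrix(0, K, Tn)
  alpha[, 1L] <- A[START, seq_len(K)] + F_mat[, 1L]
  if (Tn > 1L) {
    Ak <- A[seq_len(K), seq_len(K), drop = FALSE]
    for (t in 2:Tn) {
      alpha[, t] <- col_logsumexp(alpha[, t - 1L] + Ak) + F_mat[, t]
    }
  }
  alpha
}

# Backward recursion: beta[k, t] = log-sum over path suffixes from tag k
# at t (including the STOP transition).
crf_backward <- function(F_mat, A) {
  K <- nrow(F_mat); Tn <- ncol(F_mat); STOP <- K + 1L
  beta <- matrix(0, K, Tn)
  beta[, Tn] <- A[seq_len(K), STOP]
  if (Tn > 1L) {
    Ak <- A[seq_len(K), seq_len(K), drop = FALSE]
    for (t in (Tn - 1L):1L) {
      # row-wise logsumexp of Ak + (F[,t+1] + beta[,t+1]) over next tag
      M <- t(Ak + rep(F_mat[, t + 1L] + beta[, t + 1L], each = K))
      beta[, t] <- col_logsumexp(M)
    }
  }
  beta
}

#' Log-partition function of the CRF
#'
#' The log of the sum of exponentiated path scores over all `K^T` tag
#' sequences, computed exactly by the forward recursion in log space.
#'
#' @inheritParams sentence_score
#' @return `log Z`, a finite scalar for finite inputs.
#' @export
log_partition <- function(F_mat, A) {
  check_emissions(F_mat)
  K <- nrow(F_mat); Tn <- ncol(F_mat); STOP <- K + 1L
  alpha <- crf_forward(F_mat, A)
  logsumexp(alpha[, Tn] + A[seq_len(K), STOP])
}

#' Log conditional probability of a tag path
#'
#' `log P(y | x) = S(x, y) - log Z(x)`; always `<= 0`.
#'
#' @inheritParams sentence_score
#' @return log probability (a scalar).
#' @export
log_prob <- function(F_mat, A, y) {
  sentence_score(F_mat, A, y) - log_partition(F_mat, A)
}

#' Viterbi decoding
#'
#' Returns a maximum-score tag path via the standard dynamic program. Ties
#' are broken deterministically toward the lowest tag index at every
#' backpointer decision.
#'
#' @inheritParams sentence_score
#' @return `list(path = <integer vector>, score = <scalar>)`, with `score`
#'   equal to `sentence_score(F_mat, A, path)`.
#' @export
viterbi <- function(F_mat, A) {
  check_emissions(F_mat)
  K <- nrow(F_mat); Tn <- ncol(F_mat); START <- K + 1L; STOP <- K + 1L
  delta <- matrix(0, K, Tn)
  back <- matrix(0L, K, Tn)
  delta[, 1L] <- A[START, seq_len(K)] + F_mat[, 1L]
  if (Tn > 1L) {
    Ak <- A[seq_len(K), seq_len(K), drop = FALSE]
    for (t in 2:Tn) {
      M <- delta[, t - 1L] + Ak           # M[j, k]: arrive in k from j
      bp <- max.col(t(M), ties.method = "first")
      back[, t] <- bp
      delta[, t] <- M[cbind(bp, seq_len(K))] + F_mat[, t]
    }
  }
  fin <- delta[, Tn] + A[seq_len(K), STOP]
  path <- integer(Tn)
  path[Tn] <- which.max(fin)  # which.max takes the lowest index on ties
  if (Tn > 1L) {
    for (t in Tn:2) path[t - 1L] <- back[path[t], t]
  }
  list(path = path, score = sentence_score(F_mat, A, path))
}

#' Independent per-token decoding (the no-CRF ablation)
#'
#' Chooses the highest-scoring tag at each position independently,
#' ignoring transition scores entirely; ties go to the lowest tag index.
#'
#' @param F_mat `K x T` emission score matrix.
#' @return integer tag-index sequence of length `T`.
#' @export
softmax_decode <- function(F_mat) {
  check_emissions(F_mat)
  col_argmax(F_mat)
}

# Gradient of -log P(y|x) with respect to emissions and transitions:
# expected sufficient statistics (marginals) minus observed ones.
crf_grad <- function(F_mat, A, y) {
  K <- nrow(F_mat); Tn <- ncol(F_mat); START <- K + 1L; STOP <- K + 1L
  alpha <- crf_forward(F_mat, A)
  beta <- crf_backward(F_mat, A)
  logZ <- logsumexp(alpha[, Tn] + A[seq_len(K), STOP])
  marg <- exp(alpha + beta - logZ)                 # K x T tag marginals
  dF <- marg
  dF[cbind(y, seq_len(Tn))] <- dF[cbind(y, seq_len(Tn))] - 1
  dA <- matrix(0, K + 1L, K + 1L)
  dA[START, seq_len(K)] <- marg[, 1L]
  dA[START, y[1L]] <- dA[START, y[1L]] - 1
  dA[seq_len(K), STOP] <- marg[, Tn]
  dA[y[Tn], STOP] <- dA[y[Tn], STOP] - 1
  if (Tn > 1L) {
    Ak <- A[seq_len(K), seq_len(K), drop = FALSE]
    for (t in 2:Tn) {
      P2 <- exp(alpha[, t - 1L] + Ak +
                  rep(F_mat[, t] + beta[, t], each = K) - logZ)
      dA[seq_len(K), seq_len(K)] <- dA[seq_len(K), seq_len(K)] + P2
      dA[y[t - 1L], y[t]] <- dA[y[t - 1L], y[t]] - 1
    }
  }
  nll <- logZ - sentence_score(F_mat, A, y)
  list(dF = dF, dA = dA, nll = nll, logZ = logZ)
}

# Per-token softmax cross-entropy loss and emission gradient (no-CRF mode).
softmax_grad <- function(F_mat, y) {
  K <- nrow(F_mat); Tn <- ncol(F_mat)
  m <- F_mat[cbind(max.col(t(F_mat), ties.method = "first"), seq_len(Tn))]
  E <- exp(F_mat - rep(m, each = K))
  P <- E / rep(colSums(E), each = K)
  nll <- -sum(log(P[cbind(y, seq_len(Tn))]))
  dF <- P
  dF[cbind(y, seq_len(Tn))] <- dF[cbind(y, seq_len(Tn))] - 1
  list(dF = dF, dA = NULL, nll = nll)
}

#' Enumerate all tag paths by brute force
#'
#' Exhaustive reference implementation: scores every one of the `K^T`
#' paths with [sentence_score()]. Exponential in `T`; intended only as an
#' independent oracle for small instances in tests.
#'
#' @inheritParams sentence_score
#' @return data.frame with list-column-free encoding: one row per path,
#'   columns `score` and `path` (comma-separated indices).
#' @export
enumerate_paths <- function(F_mat, A) {
  K <- nrow(F_mat); Tn <- ncol(F_mat)
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(K)), Tn)))
  scores <- apply(grid, 1L, function(y) sentence_score(F_mat, A, as.integer(y)))
  data.frame(score = scores,
             path = apply(grid, 1L, paste, collapse = ","),
             stringsAsFactors = FALSE)
}
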