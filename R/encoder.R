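# Sentence encoder: attention-composed character representations,
# windowed word features, (bi)LSTM recurrence, and the tanh combiner that
# produces the per-token feature vectors fed to the output layer.
#
# Each public operation has a cached internal twin used by backpropagation.

# Build the character/token context-window matrix: column j of the result
# stacks the 2w+1 input columns centered on j, zero-padded at boundaries.
window_stack <- function(M, half_width) {
  d <- nrow(M); n <- ncol(M); w <- half_width
  if (w == 0L) return(M)
  out <- matrix(0, (2L * w + 1L) * d, n)
  for (k in 0:(2L * w)) {
    o <- k - w
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    if (any(ok)) out[k * d + seq_len(d), ok] <- M[, src[ok], drop = FALSE]
  }
  out
}

# Adjoint of window_stack: scatter-add window gradients back to positions.
window_unstack <- function(dX, d, half_width) {
  n <- ncol(dX); w <- half_width
  if (w == 0L) return(dX)
  dM <- matrix(0, d, n)
  for (k in 0:(2L * w)) {
    o <- k - w
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    if (any(ok)) {
      dM[, src[ok]] <- dM[, src[ok], drop = FALSE] +
        dX[k * d + seq_len(d), ok, drop = FALSE]
    }
  }
  dM
}

# Character attention forward with full cache. Ec: d_char x n matrix of
# character embeddings (columns = characters), e_w: word embedding vector.
char_attention_cached <- function(Ec, e_w, att, char_window = 2L) {
  n <- ncol(Ec)
  if (n < 1L) stop_config("char_attention requires at least one character")
  CW <- window_stack(Ec, char_window)
  h <- tanh(att$W_c %*% CW + att$b_c)
  # z_j = W_t h_j + U_t e_w + b_t; softmax over characters per dimension,
  # with the per-dimension max subtracted before exponentiation (exact in
  # real arithmetic, overflow-safe in floating point)
  z <- att$W_t %*% h + as.vector(att$U_t %*% e_w + att$b_t)
  m <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - m)
  a <- e / rowSums(e)
  R_c <- rowSums(a * Ec)
  list(R_c = R_c, a = a, h = h, Ec = Ec, CW = CW)
}

#' Attention-composed character representation of a word
#'
#' Combines the character embeddings of a word into a single vector
#' `R_c = sum_j a_j (*) e_c_j` (Hadamard product), where the attention
#' weights are vector-valued -- one weight per embedding dimension,
#' normalized over the characters within each dimension, so every
#' dimension's weights are non-negative and sum to one. Each weight is an
#' exponentiated affine score of a tanh hidden layer over the
#' `2*char_window+1`-character window (zero-padded at word boundaries)
#' together with the word's own embedding.
#'
#' @param char_embeddings `d_char x n` matrix, one column per character of
#'   the word.
#' @param word_embedding word embedding vector of the word itself.
#' @param att attention parameter list (`W_c`, `b_c`, `W_t`, `U_t`, `b_t`),
#'   see [init_model_params()].
#' @param char_window character-window half-width (default 2).
#' @return the `d_char` representation vector, with the `d_char x n`
#'   weight matrix attached as attribute `"weights"`.
#' @export
char_attention <- function(char_embeddings, word_embedding, att,
                           char_window = 2L) {
  cc <- char_attention_cached(as.matrix(char_embeddings), word_embedding,
                              att, char_window)
  structure(cc$R_c, weights = cc$a)
}

#' Per-token input representation
#'
#' Concatenates the character representation and the word embedding,
#' `R = R_c (+) e_w`; with the character model disabled the representation
#' is the word embedding alone.
#'
#' @param R_c character representation vector, or `NULL` when characters
#'   are off.
#' @param e_w word embedding vector.
#' @return numeric vector, character part first.
#' @export
word_representation <- function(R_c, e_w) {
  if (is.null(R_c)) as.numeric(e_w) else c(as.numeric(R_c), as.numeric(e_w))
}

#' Windowed token features
#'
#' For each position i, concatenates the representations of positions
#' `i-half_width .. i+half_width` (out-of-range positions contribute the
#' zero vector), producing the LSTM input
#' `x_i = R[i-2] (+) R[i-1] (+) R[i] (+) R[i+1] (+) R[i+2]` at the default
#' half-width of 2.
#'
#' @param reps `d x T` matrix of per-token representations (columns =
#'   tokens).
#' @param half_width window half-width.
#' @return `(2*half_width+1)*d x T` matrix.
#' @export
window_features <- function(reps, half_width = 2L) {
  if (ncol(reps) < 1L) stop_config("window_features requires a non-empty sentence")
  window_stack(reps, half_width)
}

# LSTM forward over the columns of X with full cache. Gate layout in the
# stacked 4H rows: input, forget, output, candidate.
lstm_forward_cached <- function(X, lstm, reverse = FALSE) {
  H <- ncol(lstm$U)
  Tn <- ncol(X)
  if (reverse) X <- X[, Tn:1, drop = FALSE]
  P <- lstm$W %*% X + lstm$b
  G <- matrix(0, 4L * H, Tn); C <- matrix(0, H, Tn); Hs <- matrix(0, H, Tn)
  i_idx <- seq_len(H); f_idx <- H + i_idx; o_idx <- 2L * H + i_idx
  g_idx <- 3L * H + i_idx
  h_prev <- numeric(H); c_prev <- numeric(H)
  for (t in seq_len(Tn)) {
    q <- P[, t] + lstm$U %*% h_prev
    i_g <- sigmoid(q[i_idx]); f_g <- sigmoid(q[f_idx])
    o_g <- sigmoid(q[o_idx]); g_g <- tanh(q[g_idx])
    c_t <- f_g * c_prev + i_g * g_g
    h_t <- o_g * tanh(c_t)
    G[, t] <- c(i_g, f_g, o_g, g_g); C[, t] <- c_t; Hs[, t] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(H = if (reverse) Hs[, Tn:1, drop = FALSE] else Hs,
       X = X, G = G, C = C, Hs = Hs, reverse = reverse)
}

#' Run an LSTM over a sequence
#'
#' Standard single-layer LSTM recurrence (input/forget/output gates and a
#' tanh candidate, no peepholes) with zero initial hidden and cell state.
#' When `reverse = TRUE` the recurrence runs right-to-left and the output
#' is re-aligned to the original token order.
#'
#' @param xs `D x T` input matrix (columns = positions).
#' @param lstm gate parameter list (`W`, `U`, `b`) with the four gates
#'   stacked row-wise, see [init_model_params()].
#' @param reverse run right-to-left?
#' @return `H x T` matrix of hidden states aligned to input order.
#' @export
lstm_forward <- function(xs, lstm, reverse = FALSE) {
  lstm_forward_cached(xs, lstm, reverse)$H
}

# Backward pass matching lstm_forward_cached. dH is aligned to original
# order; returns gradients for W, U, b and the input columns (re-aligned).
lstm_backward <- function(cache, lstm, dH) {
  Tn <- ncol(cache$X); H <- ncol(lstm$U)
  if (cache$reverse) dH <- dH[, Tn:1, drop = FALSE]
  i_idx <- seq_len(H); f_idx <- H + i_idx; o_idx <- 2L * H + i_idx
  g_idx <- 3L * H + i_idx
  dQ <- matrix(0, 4L * H, Tn)
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in Tn:1) {
    i_g <- cache$G[i_idx, t]; f_g <- cache$G[f_idx, t]
    o_g <- cache$G[o_idx, t]; g_g <- cache$G[g_idx, t]
    c_prev <- if (t > 1L) cache$C[, t - 1L] else numeric(H)
    tc <- tanh(cache$C[, t])
    dh <- dH[, t] + dh_next
    do_ <- dh * tc
    dc <- dc_next + dh * o_g * (1 - tc^2)
    di <- dc * g_g; dg <- dc * i_g; df_ <- dc * c_prev
    dc_next <- dc * f_g
    dq <- c(di * i_g * (1 - i_g), df_ * f_g * (1 - f_g),
            do_ * o_g * (1 - o_g), dg * (1 - g_g^2))
    dQ[, t] <- dq
    dh_next <- as.vector(crossprod(lstm$U, dq))
  }
  Hprev <- cbind(numeric(H), cache$Hs[, -Tn, drop = FALSE])
  dX <- crossprod(lstm$W, dQ)
  if (cache$reverse) dX <- dX[, Tn:1, drop = FALSE]
  list(W = dQ %*% t(cache$X), U = dQ %*% t(Hprev), b = rowSums(dQ), dX = dX)
}

#' Combine directional hidden states
#'
#' The final per-token feature is
#' `h_t = tanh(W_f [h_fwd; h_bwd] + b_f)`; in unidirectional mode the
#' backward part is absent and the affine map acts on `h_fwd` alone.
#'
#' @param h_fwd forward hidden vector (or `H x T` matrix).
#' @param h_bwd backward hidden vector/matrix, or `NULL`.
#' @param comb combiner parameters (`W`, `b`).
#' @return combined feature vector/matrix of the combiner dimension.
#' @export
combine_hidden <- function(h_fwd, h_bwd = NULL, comb) {
  hx <- if (is.null(h_bwd)) h_fwd else rbind(as.matrix(h_fwd), as.matrix(h_bwd))
  out <- tanh(comb$W %*% as.matrix(hx) + comb$b)
  if (is.null(dim(h_fwd))) as.vector(out) else out
}

# Full forward pass over one indexed sentence, with caches for backprop.
forward_sentence <- function(sent, params, config, keep_cache = FALSE) {
  Tn <- length(sent$word_ids)
  if (Tn < 1L) stop_config("cannot encode an empty sentence")
  Ew <- t(params$word$matrix[sent$word_ids, , drop = FALSE])
  att_caches <- NULL
  if (config$use_char) {
    att_caches <- vector("list", Tn)
    Rc <- matrix(0, config$char_dim, Tn)
    for (i in seq_len(Tn)) {
      Ec <- t(params$char$matrix[sent$char_ids[[i]], , drop = FALSE])
      cc <- char_attention_cached(Ec, Ew[, i], params$att, config$char_window)
      Rc[, i] <- cc$R_c
      att_caches[[i]] <- cc
    }
    R <- rbind(Rc, Ew)
  } else {
    R <- Ew
  }
  X <- window_stack(R, config$word_window)
  fwd <- lstm_forward_cached(X, params$lstm_f, reverse = FALSE)
  bwd <- if (config$bidirectional) {
    lstm_forward_cached(X, params$lstm_b, reverse = TRUE)
  }
  Hcat <- if (config$bidirectional) rbind(fwd$H, bwd$H) else fwd$H
  h_out <- tanh(params$comb$W %*% Hcat + params$comb$b)
  F_mat <- params$emit$W %*% h_out + params$emit$b
  out <- list(F = F_mat, hidden = h_out)
  if (keep_cache) {
    out$cache <- list(Ew = Ew, att = att_caches, X = X, fwd = fwd, bwd = bwd,
                      Hcat = Hcat)
  }
  out
}

#' Encode a sentence into per-token feature vectors
#'
#' Composes character attention, the word context window, the (bi)LSTM
#' and the combiner to produce the hidden feature sequence `h_1 .. h_T`
#' that the output layer scores. Deterministic given parameters.
#'
#' @param sentence an indexed sentence from [index_corpus()].
#' @param params a `bioner_params`.
#' @param config a [bioner_config()] consistent with `params`.
#' @return `combiner_dim x T` matrix of feature vectors.
#' @export
encode_sentence <- function(sentence, params, config) {
  forward_sentence(sentence, params, config)$hidden
}

#' Export per-token features as a tab-separated matrix
#'
#' Inspection hook: writes the encoder's feature vectors for a corpus,
#' one token per row (`sentence`, `position`, `token`, then the feature
#' dimensions), so representations can be visualized externally.
#'
#' @param corpus indexed corpus.
#' @param params,config model parameters and configuration.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_features <- function(corpus, params, config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- config$combiner_dim
  writeLines(paste(c("sentence", "position", "token",
                     sprintf("h%03d", seq_len(d))), collapse = "\t"), con)
  for (si in seq_along(corpus)) {
    h <- encode_sentence(corpus[[si]], params, config)
    for (t in seq_len(ncol(h))) {
      writeLines(paste(c(si, t, corpus[[si]]$tokens[t],
                         format(h[, t], digits = 8)), collapse = "\t"), con)
    }
  }
  invisible(path)
}
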