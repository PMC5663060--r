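# Model configuration and the trainable parameter container.

#' Model and training configuration
#'
#' Collects every architectural switch and training hyperparameter in one
#' place, in the spirit of `glm.control()`. Defaults are the published
#' settings of the method: 30-dimensional character embeddings, hidden and
#' combiner layers of size 100, +/-2 word and character windows, AdaGrad
#' initial learning rate 0.01 and L2 regularization 1e-8.
#'
#' @param use_char include the attention-composed character representation?
#' @param bidirectional run forward and backward LSTMs (`TRUE`) or a single
#'   forward LSTM?
#' @param word_window half-width of the token context window (2 gives the
#'   5-token window `R[i-2] .. R[i+2]`).
#' @param char_window half-width of the character context window inside the
#'   attention scorer.
#' @param hidden_dim LSTM hidden state size per direction.
#' @param combiner_dim size of the tanh hidden layer combining the two
#'   LSTM directions.
#' @param char_dim character embedding dimension.
#' @param char_hidden_dim size of the character-window hidden layer inside
#'   the attention scorer.
#' @param learning_rate AdaGrad initial learning rate (alpha).
#' @param l2 L2 regularization strength (lambda).
#' @param seed RNG seed governing initialization and epoch shuffling.
#' @param max_epochs training epoch budget.
#' @param patience epochs without development-set F1 improvement before
#'   early stopping.
#' @param early_stop_f1 stop as soon as development F1 reaches this value
#'   (1 = stop only on a perfect development score).
#' @param fine_tune_words update the pre-trained word embeddings during
#'   training (`TRUE`) or keep them fixed?
#' @param decoder `"crf"` for the linear-chain CRF output layer, or
#'   `"softmax"` for independent per-token decisions (the no-CRF ablation).
#' @param crf_start_stop learn explicit START/STOP transition scores
#'   (`TRUE`) or fix them at zero?
#' @param ridge_sign `"penalty"` subtracts the ridge term from the
#'   maximized likelihood (the standard regularizer); `"bonus"` adds it,
#'   reproducing the printed objective literally for auditability.
#' @param digits digit-replacement convention, see [normalize_token()].
#' @return a list of class `bioner_config`.
#' @export
bioner_config <- function(use_char = TRUE,
                          bidirectional = TRUE,
                          word_window = 2L,
                          char_window = 2L,
                          hidden_dim = 100L,
                          combiner_dim = 100L,
                          char_dim = 30L,
                          char_hidden_dim = 30L,
                          learning_rate = 0.01,
                          l2 = 1e-8,
                          seed = 1L,
                          max_epochs = 100L,
                          patience = 10L,
                          early_stop_f1 = 1.0,
                          fine_tune_words = TRUE,
                          decoder = c("crf", "softmax"),
                          crf_start_stop = TRUE,
                          ridge_sign = c("penalty", "bonus"),
                          digits = c("digit_run", "whole_token")) {
  decoder <- match.arg(decoder)
  ridge_sign <- match.arg(ridge_sign)
  digits <- match.arg(digits)
  if (learning_rate <= 0) stop_config("learning_rate must be positive")
  if (l2 < 0) stop_config("l2 must be non-negative")
  if (word_window < 0 || char_window < 0) stop_config("window half-widths must be >= 0")
  for (nm in c("hidden_dim", "combiner_dim", "char_dim", "char_hidden_dim")) {
    v <- get(nm)
    if (!is_count(v) || v < 1L) stop_config("%s must be a positive integer", nm)
  }
  if (!is_count(patience) || patience < 1L) stop_config("patience must be >= 1")
  structure(
    list(use_char = use_char, bidirectional = bidirectional,
         word_window = as.integer(word_window),
         char_window = as.integer(char_window),
         hidden_dim = as.integer(hidden_dim),
         combiner_dim = as.integer(combiner_dim),
         char_dim = as.integer(char_dim),
         char_hidden_dim = as.integer(char_hidden_dim),
         learning_rate = learning_rate, l2 = l2, seed = as.integer(seed),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         early_stop_f1 = early_stop_f1,
         fine_tune_words = fine_tune_words, decoder = decoder,
         crf_start_stop = crf_start_stop, ridge_sign = ridge_sign,
         digits = digits),
    class = "bioner_config"
  )
}

# Uniform draw in the Glorot bound of the owning matrix's shape; biases use
# the same rule as their weight matrix.
glorot_draw <- function(n, n_rows, n_cols) {
  b <- sqrt(6 / (n_rows + n_cols))
  stats::runif(n, -b, b)
}

glorot_matrix <- function(n_rows, n_cols) {
  matrix(glorot_draw(n_rows * n_cols, n_rows, n_cols), n_rows, n_cols)
}

glorot_bias <- function(n_rows, n_cols) glorot_draw(n_rows, n_rows, n_cols)

#' Initialize all model parameters
#'
#' Builds the full parameter set: the two embedding tables, the character
#' attention block, the LSTM gate matrices for each direction, the
#' direction combiner, the emission map from hidden features to tag
#' scores, and the CRF transition matrix (augmented with a START row and a
#' STOP column). All dense layers and biases are Glorot-uniform; the draw
#' is a pure function of the configuration seed.
#'
#' @param config a [bioner_config()].
#' @param word_table word `embedding_table` (its `trainable` flag is set
#'   from `config$fine_tune_words`).
#' @param char_alphabet a `char_alphabet`, required when `config$use_char`.
#' @param tag_alphabet a [tag_alphabet()].
#' @return a list of class `bioner_params` with components `word`, `char`,
#'   `att`, `lstm_f`, `lstm_b`, `comb`, `emit`, `trans` (unused components
#'   are `NULL`).
#' @export
init_model_params <- function(config, word_table, char_alphabet = NULL,
                              tag_alphabet) {
  K <- length(tag_alphabet$labels)
  d_w <- word_table$dim
  word_table$trainable <- isTRUE(config$fine_tune_words)
  rep_dim <- d_w + if (config$use_char) config$char_dim else 0L
  in_dim <- (2L * config$word_window + 1L) * rep_dim
  H <- config$hidden_dim
  with_seed(config$seed, {
    char_tab <- NULL; att <- NULL
    if (config$use_char) {
      if (is.null(char_alphabet)) stop_config("use_char requires a char_alphabet")
      char_tab <- init_char_embeddings(char_alphabet$size, config$char_dim,
                                       seed = sample.int(2^30, 1L))
      cw <- (2L * config$char_window + 1L) * config$char_dim
      Hc <- config$char_hidden_dim
      att <- list(
        W_c = glorot_matrix(Hc, cw), b_c = glorot_bias(Hc, cw),
        W_t = glorot_matrix(config$char_dim, Hc),
        U_t = glorot_matrix(config$char_dim, d_w),
        b_t = glorot_bias(config$char_dim, Hc)
      )
    }
    lstm_gates <- function() list(
      W = glorot_matrix(4L * H, in_dim),
      U = glorot_matrix(4L * H, H),
      b = glorot_bias(4L * H, in_dim)
    )
    lstm_f <- lstm_gates()
    lstm_b <- if (config$bidirectional) lstm_gates() else NULL
    comb_in <- if (config$bidirectional) 2L * H else H
    comb <- list(W = glorot_matrix(config$combiner_dim, comb_in),
                 b = glorot_bias(config$combiner_dim, comb_in))
    emit <- list(W = glorot_matrix(K, config$combiner_dim),
                 b = glorot_bias(K, config$combiner_dim))
    trans <- glorot_matrix(K + 1L, K + 1L)
    trans[K + 1L, K + 1L] <- 0  # START -> STOP never occurs (T >= 1)
    if (!config$crf_start_stop) {
      trans[K + 1L, ] <- 0  # START row
      trans[, K + 1L] <- 0  # STOP column
    }
    structure(
      list(word = word_table, char = char_tab, att = att,
           lstm_f = lstm_f, lstm_b = lstm_b, comb = comb, emit = emit,
           trans = trans),
      class = "bioner_params"
    )
  })
}

# ---- parameter-tree walking -------------------------------------------------
# Parameters form a nested list whose leaves are numeric arrays (embedding
# tables contribute their matrix). The walkers below define one canonical
# leaf order used by flattening, gradient containers, and AdaGrad state.

leaf_values <- function(p) {
  if (is.null(p)) return(list())
  if (inherits(p, "embedding_table")) return(list(p$matrix))
  if (is.list(p)) return(do.call(c, lapply(unclass(p), leaf_values)))
  list(p)
}

#' Flatten model parameters to a numeric vector
#'
#' @param params a `bioner_params` (or any nested list of numeric arrays).
#' @return numeric vector concatenating every leaf in canonical order.
#' @export
flatten_params <- function(params) {
  unlist(lapply(leaf_values(params), as.vector), use.names = FALSE)
}

#' Rebuild model parameters from a flat vector
#'
#' @param flat numeric vector as produced by [flatten_params()].
#' @param template a `bioner_params` providing shapes.
#' @return a `bioner_params` with the same structure as `template`.
#' @export
unflatten_params <- function(flat, template) {
  pos <- 0L
  fill <- function(p) {
    if (is.null(p)) return(NULL)
    if (inherits(p, "embedding_table")) {
      n <- length(p$matrix)
      p$matrix[] <- flat[(pos + 1L):(pos + n)]
      pos <<- pos + n
      return(p)
    }
    if (is.list(p)) {
      cl <- class(p)
      out <- lapply(unclass(p), fill)
      class(out) <- cl
      return(out)
    }
    n <- length(p)
    p[] <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    p
  }
  out <- fill(template)
  if (pos != length(flat)) stop_config("flat vector length %d does not match template (%d)",
                                       length(flat), pos)
  out
}

# A same-shaped container of zeros (used for gradients and AdaGrad state).
zero_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (inherits(p, "embedding_table")) { p$matrix[] <- 0; return(p) }
  if (is.list(p)) {
    cl <- class(p); out <- lapply(unclass(p), zero_like); class(out) <- cl
    return(out)
  }
  p[] <- 0
  p
}

# 0/1 mask over the parameter tree marking coordinates that are trainable
# (and therefore also ridge-penalized): frozen word embeddings, padding
# rows, the unused transition corner, and -- under the softmax decoder or
# with START/STOP disabled -- the corresponding transition entries get 0.
trainable_mask <- function(params, config) {
  m <- zero_like(params)
  set_ones <- function(x) { x[] <- 1; x }
  if (params$word$trainable) {
    m$word$matrix[] <- 1
    if (!is.na(params$word$pad_id)) m$word$matrix[params$word$pad_id, ] <- 0
  }
  if (!is.null(m$char)) m$char$matrix[] <- 1
  if (!is.null(m$att)) m$att <- lapply(m$att, set_ones)
  m$lstm_f <- lapply(m$lstm_f, set_ones)
  if (!is.null(m$lstm_b)) m$lstm_b <- lapply(m$lstm_b, set_ones)
  m$comb <- lapply(m$comb, set_ones)
  m$emit <- lapply(m$emit, set_ones)
  if (config$decoder == "crf") {
    K <- nrow(m$trans) - 1L
    m$trans[] <- 1
    m$trans[K + 1L, K + 1L] <- 0
    if (!config$crf_start_stop) {
      m$trans[K + 1L, ] <- 0
      m$trans[, K + 1L] <- 0
    }
  }
  m
}

# Sum of squares of trainable coordinates (the ridge norm ||Theta||^2).
param_sumsq <- function(params, mask) {
  lv <- leaf_values(params)
  mv <- leaf_values(mask)
  s <- 0
  for (i in seq_along(lv)) s <- s + sum((lv[[i]] * mv[[i]])^2)
  s
}
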