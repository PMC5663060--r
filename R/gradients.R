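# Hand-derived backpropagation for the complete model: the loss gradient
# flows from the output layer (CRF marginals or per-token softmax) through
# the emission map, the combiner, both LSTM directions, the context
# window, the character attention block, and into both embedding tables.

ridge_sign_value <- function(config) {
  if (config$ridge_sign == "penalty") 1 else -1
}

#' Regularized negative log-likelihood of one sentence
#'
#' `-log P(y | x) + (lambda/2) ||Theta||^2`, where the ridge norm runs over
#' trainable coordinates only (frozen embeddings, padding rows and unused
#' transition entries are excluded). Under `ridge_sign = "bonus"` the ridge
#' term is subtracted instead, reproducing the printed objective literally.
#'
#' @param sentence an indexed sentence (see [index_corpus()]).
#' @param params a `bioner_params`.
#' @param config a [bioner_config()].
#' @return scalar loss.
#' @export
sentence_loss <- function(sentence, params, config) {
  fw <- forward_sentence(sentence, params, config)
  y <- sentence$tag_ids
  nll <- if (config$decoder == "crf") {
    log_partition(fw$F, params$trans) - sentence_score(fw$F, params$trans, y)
  } else {
    softmax_grad(fw$F, y)$nll
  }
  if (config$l2 > 0) {
    mask <- trainable_mask(params, config)
    nll <- nll + ridge_sign_value(config) * (config$l2 / 2) *
      param_sumsq(params, mask)
  }
  nll
}

#' Analytic gradient of the sentence loss
#'
#' Backpropagates [sentence_loss()] through every layer. Parameters frozen
#' by the configuration (word embeddings with `fine_tune_words = FALSE`,
#' the transition matrix under the softmax decoder, START/STOP entries
#' when disabled, padding rows) receive exactly zero gradient.
#'
#' @inheritParams sentence_loss
#' @return `list(loss = <scalar>, grads = <bioner_params-shaped tree>,
#'   flat = <numeric vector>)` with `flat = flatten_params(grads)`.
#' @export
sentence_gradients <- function(sentence, params, config) {
  raw <- backprop_raw(sentence, params, config)
  mflat <- flatten_params(trainable_mask(params, config))
  gflat <- flatten_params(raw$g) * mflat
  loss <- raw$nll
  if (config$l2 > 0) {
    s <- ridge_sign_value(config)
    tflat <- flatten_params(params) * mflat
    loss <- loss + s * (config$l2 / 2) * sum(tflat^2)
    gflat <- gflat + s * config$l2 * tflat
  }
  list(loss = loss, grads = unflatten_params(gflat, raw$g), flat = gflat)
}

# Unmasked, unregularized backprop: returns the raw gradient tree and the
# negative log-likelihood. The training loop applies the (precomputed)
# freeze mask and ridge term on flat vectors for speed.
backprop_raw <- function(sentence, params, config) {
  fw <- forward_sentence(sentence, params, config, keep_cache = TRUE)
  cache <- fw$cache
  y <- sentence$tag_ids
  Tn <- length(y)
  og <- if (config$decoder == "crf") crf_grad(fw$F, params$trans, y)
        else softmax_grad(fw$F, y)
  g <- zero_like(params)
  if (!is.null(og$dA)) g$trans <- og$dA
  h_out <- fw$hidden
  g$emit$W <- og$dF %*% t(h_out)
  g$emit$b <- rowSums(og$dF)
  dh <- crossprod(params$emit$W, og$dF)
  dpre <- dh * (1 - h_out^2)
  g$comb$W <- dpre %*% t(cache$Hcat)
  g$comb$b <- rowSums(dpre)
  dHcat <- crossprod(params$comb$W, dpre)
  H <- config$hidden_dim
  bf <- lstm_backward(cache$fwd, params$lstm_f,
                      dHcat[seq_len(H), , drop = FALSE])
  g$lstm_f$W <- bf$W; g$lstm_f$U <- bf$U; g$lstm_f$b <- bf$b
  dX <- bf$dX
  if (config$bidirectional) {
    bb <- lstm_backward(cache$bwd, params$lstm_b,
                        dHcat[H + seq_len(H), , drop = FALSE])
    g$lstm_b$W <- bb$W; g$lstm_b$U <- bb$U; g$lstm_b$b <- bb$b
    dX <- dX + bb$dX
  }
  d_c <- if (config$use_char) config$char_dim else 0L
  rep_dim <- d_c + params$word$dim
  dR <- window_unstack(dX, rep_dim, config$word_window)
  if (config$use_char) {
    dRc <- dR[seq_len(d_c), , drop = FALSE]
    dEw <- dR[d_c + seq_len(params$word$dim), , drop = FALSE]
    for (i in seq_len(Tn)) {
      cc <- cache$att[[i]]
      gvec <- dRc[, i]
      a <- cc$a
      dA_att <- cc$Ec * gvec                      # dL/da, per dimension
      dEc <- a * gvec                             # via R_c = sum_j a_j (*) e_j
      # softmax over characters, independently per embedding dimension
      dz <- a * (dA_att - rowSums(a * dA_att))
      g$att$W_t <- g$att$W_t + dz %*% t(cc$h)
      db_t <- rowSums(dz)
      g$att$b_t <- g$att$b_t + db_t
      g$att$U_t <- g$att$U_t + db_t %*% t(cache$Ew[, i])
      dEw[, i] <- dEw[, i] + as.vector(crossprod(params$att$U_t, db_t))
      dh_att <- crossprod(params$att$W_t, dz)
      dpre_h <- dh_att * (1 - cc$h^2)
      g$att$W_c <- g$att$W_c + dpre_h %*% t(cc$CW)
      g$att$b_c <- g$att$b_c + rowSums(dpre_h)
      dCW <- crossprod(params$att$W_c, dpre_h)
      dEc <- dEc + window_unstack(dCW, d_c, config$char_window)
      ids <- sentence$char_ids[[i]]
      agg <- rowsum(t(dEc), group = ids)
      rid <- as.integer(rownames(agg))
      g$char$matrix[rid, ] <- g$char$matrix[rid, , drop = FALSE] + agg
    }
  } else {
    dEw <- dR
  }
  aggw <- rowsum(t(dEw), group = sentence$word_ids)
  rid <- as.integer(rownames(aggw))
  g$word$matrix[rid, ] <- g$word$matrix[rid, , drop = FALSE] + aggw
  list(nll = og$nll, g = g)
}
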