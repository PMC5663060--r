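# S3 methods for fitted models.

#' @export
print.bioner <- function(x, ...) {
  cfg <- x$config
  arch <- paste0(if (cfg$bidirectional) "BLSTM" else "LSTM",
                 if (cfg$use_char) "+Char" else "-Char",
                 if (cfg$decoder == "crf") "+CRF" else "+softmax")
  cat("Character-attentive neural sequence tagger (", arch, ")\n", sep = "")
  cat(sprintf("  entity types: %s\n",
              paste(x$tag_alphabet$types, collapse = ", ")))
  cat(sprintf("  word vectors: %d x %d (%s), char dim %d, hidden %d, combiner %d\n",
              nrow(x$params$word$matrix), x$params$word$dim,
              if (x$params$word$trainable) "fine-tuned" else "fixed",
              if (cfg$use_char) cfg$char_dim else 0L,
              cfg$hidden_dim, cfg$combiner_dim))
  if (!is.null(x$log) && nrow(x$log)) {
    cat(sprintf("  trained %d epoch(s); best dev F1 %.4f at epoch %d\n",
                nrow(x$log), max(x$log$dev_f1), x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.bioner <- function(object, ...) {
  n_par <- length(flatten_params(object$params))
  out <- list(model = object, n_parameters = n_par, log = object$log,
              best_epoch = object$best_epoch)
  class(out) <- "summary.bioner"
  out
}

#' @export
print.summary.bioner <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d trainable tensors, %d parameters in total\n",
              length(leaf_values(x$model$params)), x$n_parameters))
  if (!is.null(x$log) && nrow(x$log)) {
    cat("\nTraining log (last 5 epochs):\n")
    print(utils::tail(x$log, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' Extract model parameters
#'
#' @param object a fitted `bioner` model.
#' @param flat return one flat numeric vector instead of the named list of
#'   tensors.
#' @param ... unused.
#' @return named list of parameter tensors, or a numeric vector.
#' @export
coef.bioner <- function(object, flat = FALSE, ...) {
  if (flat) return(flatten_params(object$params))
  object$params
}

#' Tag sentences with a fitted model
#'
#' Decodes BIEOS tag sequences for new sentences using the model's own
#' decoder (Viterbi for the CRF layer, per-token argmax for the softmax
#' ablation).
#'
#' @param object a fitted `bioner` model.
#' @param newdata a list of sentences (`list(tokens = ...)`; tags, if
#'   present, are ignored) or a path to a CoNLL-style file.
#' @param ... unused.
#' @return list of sentences with `tokens` and predicted `tags`.
#' @export
predict.bioner <- function(object, newdata, ...) {
  if (is.character(newdata)) newdata <- read_conll(newdata, tag_column = NA)
  if (!length(newdata)) return(list())
  newdata <- lapply(newdata, function(s) {
    list(tokens = s$tokens, tags = rep("O", length(s$tokens)))
  })
  idx <- index_corpus(newdata, object$params$word, object$char_alphabet,
                      object$tag_alphabet, digits = object$config$digits)
  paths <- decode_corpus(idx, object$params, object$config)
  lapply(seq_along(newdata), function(i) {
    list(tokens = newdata[[i]]$tokens,
         tags = object$tag_alphabet$labels[paths[[i]]])
  })
}

#' Plot the training trajectory
#'
#' Draws per-epoch mean training loss and development-set span F1.
#'
#' @param x a fitted `bioner` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bioner <- function(x, ...) {
  if (is.null(x$log) || !nrow(x$log)) {
    stop_config("model has no training log to plot")
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$log$epoch, x$log$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "mean training loss", ...)
  graphics::plot(x$log$epoch, x$log$dev_f1, type = "b", pch = 16,
                 ylim = c(0, 1), xlab = "epoch", ylab = "dev span F1", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  invisible(x)
}
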