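# Online AdaGrad training with development-set model selection, and the
# user-facing fitting function.

#' One AdaGrad coordinate update
#'
#' Implements the update
#' `theta <- theta - alpha / sqrt(sum of squared gradients so far) * g`,
#' where the accumulator includes the current gradient. No smoothing
#' constant is added; a zero gradient with an empty accumulator performs
#' no update (guarding the 0/0 case).
#'
#' @param theta current parameter value(s).
#' @param g current (sub)gradient, same shape.
#' @param state accumulated squared gradients before this step.
#' @param alpha initial learning rate (> 0).
#' @return `list(theta = <updated>, state = <state + g^2>)`.
#' @examples
#' s <- adagrad_step(0, 3, 0, 0.01)   # first step: size alpha * sign(g)
#' adagrad_step(s$theta, 4, s$state, 0.01)$theta - s$theta  # -0.01 * 4/5
#' @export
adagrad_step <- function(theta, g, state, alpha) {
  if (alpha <= 0) stop_config("alpha must be positive")
  state <- state + g^2
  denom <- sqrt(state)
  upd <- alpha * g / denom
  upd[!is.finite(upd)] <- 0  # g = 0 with empty accumulator: no update
  list(theta = theta - upd, state = state)
}

# Decode one indexed corpus with the given parameters; returns a list of
# integer tag-index paths.
decode_corpus <- function(corpus, params, config) {
  lapply(corpus, function(s) {
    F_mat <- forward_sentence(s, params, config)$F
    if (config$decoder == "crf") viterbi(F_mat, params$trans)$path
    else softmax_decode(F_mat)
  })
}

# Span F1 of decoded paths against gold tag ids.
corpus_f1 <- function(corpus, paths, tag_alphabet) {
  gold <- lapply(corpus, function(s) list(tokens = s$tokens, tags = s$tags))
  pred <- lapply(seq_along(corpus), function(i) {
    list(tokens = corpus[[i]]$tokens,
         tags = tag_alphabet$labels[paths[[i]]])
  })
  score_corpus(gold, pred)
}

#' Fit a character-attentive (bi)LSTM-CRF tagger
#'
#' Trains all model parameters by regularized maximum likelihood with
#' online AdaGrad: one update per sentence, in a freshly shuffled order
#' each epoch. After every epoch the development split is decoded and
#' span F1 recorded; the parameters achieving the best development F1 are
#' returned. Training stops at the epoch budget, when development F1 has
#' not improved for `patience` epochs, or when it reaches
#' `early_stop_f1`. The whole run is a deterministic function of
#' (corpora, embeddings, configuration, seed).
#'
#' @param train list of training sentences (`tokens`/`tags`, BIEOS tags).
#' @param dev development sentences; `NULL` splits a seeded 10% off the
#'   training set.
#' @param embeddings a word `embedding_table` (see [load_word2vec_text()])
#'   or a path to a word2vec text file.
#' @param config a [bioner_config()].
#' @return an object of class `bioner`: a list with the fitted `params`,
#'   `config`, `tag_alphabet`, `char_alphabet`, the per-epoch training
#'   `log` (data.frame: epoch, train_loss, dev_precision, dev_recall,
#'   dev_f1, param_norm -- the trainable-parameter L2 norm after the
#'   epoch), and `best_epoch`.
#' @seealso [predict.bioner()], [save_model()], [bioner_config()]
#' @export
bioner <- function(train, dev = NULL, embeddings, config = bioner_config()) {
  cl <- match.call()
  if (!length(train)) stop_config("empty training corpus")
  if (is.character(embeddings)) {
    embeddings <- load_word2vec_text(embeddings, seed = config$seed)
  }
  for (i in seq_along(train)) {
    ok <- is_bieos_valid(train[[i]]$tags)
    if (!isTRUE(ok)) {
      stop_config("training sentence %d is not BIEOS-valid (%s)",
                  i, attr(ok, "reason"))
    }
  }
  if (is.null(dev)) {
    idx <- with_seed(config$seed, sample(length(train),
                                         max(1L, round(0.1 * length(train)))))
    dev <- train[idx]
    train <- train[-idx]
    if (!length(train)) stop_config("training corpus too small to split")
  }
  types <- sort(unique(unlist(lapply(train, function(s) {
    st <- split_tag(s$tags); st$type[!is.na(st$type)]
  }), use.names = FALSE)))
  if (!length(types)) stop_config("training corpus contains no entities")
  tag_ab <- tag_alphabet(types)
  char_ab <- build_char_alphabet(train)
  params <- init_model_params(config, embeddings, char_ab, tag_ab)
  train_idx <- index_corpus(train, params$word, char_ab, tag_ab,
                            digits = config$digits)
  dev_idx <- index_corpus(dev, params$word, char_ab, tag_ab,
                          digits = config$digits)
  fit <- with_seed(config$seed + 1L,
                   train_loop(train_idx, dev_idx, params, config, tag_ab))
  structure(
    list(params = fit$params, config = config, tag_alphabet = tag_ab,
         char_alphabet = char_ab, log = fit$log,
         best_epoch = fit$best_epoch, call = cl),
    class = "bioner"
  )
}

# Rebuild a parameter tree from an ordered list of leaf arrays (the
# inverse of leaf_values).
set_leaves <- function(p, leaves, pos = 1L) {
  fill <- function(p) {
    if (is.null(p)) return(NULL)
    if (inherits(p, "embedding_table")) {
      p$matrix <- leaves[[pos]]; pos <<- pos + 1L
      return(p)
    }
    if (is.list(p)) {
      cl <- class(p); out <- lapply(unclass(p), fill); class(out) <- cl
      return(out)
    }
    v <- leaves[[pos]]; pos <<- pos + 1L
    v
  }
  fill(p)
}

# The inner optimization loop. One AdaGrad update per sentence, applied
# leaf-wise over the parameter tree. RNG state is managed by the caller.
train_loop <- function(train_idx, dev_idx, params, config, tag_ab) {
  mask <- leaf_values(trainable_mask(params, config))
  cur <- params
  tl <- leaf_values(cur)
  state <- lapply(tl, function(x) { x[] <- 0; x })
  alpha <- config$learning_rate
  lam <- config$l2
  s_sign <- ridge_sign_value(config)
  n <- length(train_idx)
  best_f1 <- -Inf; best_leaves <- tl; best_epoch <- 0L
  log_rows <- vector("list", config$max_epochs)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    for (si in ord) {
      raw <- backprop_raw(train_idx[[si]], cur, config)
      gl <- leaf_values(raw$g)
      loss <- raw$nll
      for (i in seq_along(tl)) {
        gi <- gl[[i]] * mask[[i]]
        if (lam > 0) {
          tm <- tl[[i]] * mask[[i]]
          loss <- loss + s_sign * (lam / 2) * sum(tm * tm)
          gi <- gi + (s_sign * lam) * tm
        }
        st <- state[[i]] + gi * gi
        state[[i]] <- st
        upd <- alpha * gi / sqrt(st)
        upd[st == 0] <- 0  # zero gradient with empty accumulator: no update
        tl[[i]] <- tl[[i]] - upd
      }
      total_loss <- total_loss + loss
      cur <- set_leaves(cur, tl)
    }
    dev_paths <- decode_corpus(dev_idx, cur, config)
    dev_eval <- corpus_f1(dev_idx, dev_paths, tag_ab)
    nrm <- sqrt(sum(vapply(seq_along(tl), function(i) {
      sum((tl[[i]] * mask[[i]])^2)
    }, numeric(1))))
    log_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = total_loss / n,
      dev_precision = dev_eval$precision, dev_recall = dev_eval$recall,
      dev_f1 = dev_eval$f1, param_norm = nrm
    )
    if (dev_eval$f1 > best_f1) {
      best_f1 <- dev_eval$f1; best_leaves <- tl; best_epoch <- epoch
    }
    if (dev_eval$f1 >= config$early_stop_f1) break
    if (epoch - best_epoch >= config$patience) break
  }
  list(params = set_leaves(params, best_leaves),
       log = do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))]),
       best_epoch = best_epoch)
}

#' Save a fitted model
#'
#' Serializes the full model archive -- tensors, alphabets, configuration
#' -- as a single versioned file.
#'
#' @param model a fitted `bioner` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "bioner")) stop_config("not a bioner model")
  saveRDS(list(format = "bioner-model", version = 1L, model = model), path)
  invisible(path)
}

#' Load a fitted model
#'
#' @param path file written by [save_model()].
#' @return the `bioner` object.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop_config("cannot read model file %s: %s", path, conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, "bioner-model")) {
    stop_config("%s is not a model archive", path)
  }
  if (!identical(obj$version, 1L)) {
    stop_config("unsupported model archive version %s", obj$version)
  }
  m <- obj$model
  if (!inherits(m, "bioner") || is.null(m$params) || is.null(m$config)) {
    stop_config("model archive is incomplete")
  }
  # shape consistency between config and tensors
  K <- length(m$tag_alphabet$labels)
  if (nrow(m$params$trans) != K + 1L ||
      nrow(m$params$emit$W) != K ||
      ncol(m$params$emit$W) != m$config$combiner_dim) {
    stop_config("model archive shapes do not match its configuration")
  }
  if (m$config$use_char && is.null(m$params$char)) {
    stop_config("model archive is missing its character parameters")
  }
  m
}
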