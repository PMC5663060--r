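# Shared fixture builders. Everything is generated in code at test time;
# no binary or stored data.

# A tiny hand-written two-sentence corpus with mixed orthography.
tiny_sentences <- function() {
  list(
    list(tokens = c("Abc1", "de", "Fg2h"),
         tags = c("B-protein", "E-protein", "O")),
    list(tokens = c("xx"), tags = c("S-DNA"))
  )
}

# A small model over the tiny corpus, with every block active by default.
tiny_model_setup <- function(decoder = "crf", use_char = TRUE,
                             bidirectional = TRUE, fine_tune_words = TRUE,
                             l2 = 1e-3, seed = 7, word_window = 1L,
                             char_window = 1L, ...) {
  cfg <- bioner_config(use_char = use_char, bidirectional = bidirectional,
                       word_window = word_window, char_window = char_window,
                       hidden_dim = 4L, combiner_dim = 3L, char_dim = 3L,
                       char_hidden_dim = 4L, l2 = l2, seed = seed,
                       fine_tune_words = fine_tune_words, decoder = decoder,
                       ...)
  sents <- tiny_sentences()
  vocab <- corpus_vocabulary(sents)
  emb_file <- tempfile(fileext = ".vec")
  generate_embeddings(vocab, dim = 4L, seed = 3L, path = emb_file)
  word_tab <- load_word2vec_text(emb_file, trainable = fine_tune_words,
                                 seed = 5L)
  tag_ab <- tag_alphabet(c("protein", "DNA"))
  char_ab <- build_char_alphabet(sents)
  params <- init_model_params(cfg, word_tab, char_ab, tag_ab)
  idx <- index_corpus(sents, params$word, char_ab, tag_ab)
  list(config = cfg, params = params, idx = idx, tag_alphabet = tag_ab,
       char_alphabet = char_ab, sentences = sents)
}

# Independent straight-line path scorer: plain loops over the printed
# scoring rule, sharing no code with the package's CRF routines.
brute_path_score <- function(F_mat, A, y) {
  K <- nrow(F_mat)
  s <- A[K + 1L, y[1L]] + F_mat[y[1L], 1L]
  if (length(y) > 1L) {
    for (t in 2:length(y)) s <- s + A[y[t - 1L], y[t]] + F_mat[y[t], t]
  }
  s + A[y[length(y)], K + 1L]
}

# All K^T paths as an integer matrix (rows = paths).
all_paths <- function(K, Tn) {
  as.matrix(do.call(expand.grid, rep(list(seq_len(K)), Tn)))
}

# Random valid IOB2 tag sequence over the given types.
random_iob2 <- function(n, types) {
  tags <- character(n)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < 0.5) {
      tags[i] <- "O"; i <- i + 1L
    } else {
      ty <- sample(types, 1L)
      len <- min(sample(1:4, 1L), n - i + 1L)
      tags[i:(i + len - 1L)] <- c(paste0("B-", ty),
                                  rep(paste0("I-", ty), len - 1L))
      i <- i + len
    }
  }
  tags
}

# Central finite-difference gradient of sentence_loss over all coordinates
# marked by `active` (indices into the flat parameter vector).
fd_gradient <- function(sent, params, config, active, h = 1e-5) {
  flat <- flatten_params(params)
  fd <- numeric(length(flat))
  for (i in active) {
    fp <- flat; fp[i] <- fp[i] + h
    fm <- flat; fm[i] <- fm[i] - h
    fd[i] <- (sentence_loss(sent, unflatten_params(fp, params), config) -
                sentence_loss(sent, unflatten_params(fm, params), config)) /
      (2 * h)
  }
  fd
}

# Relative gradient error with a unit floor (gradients here are O(1);
# the floor keeps coordinates with vanishing true gradient well-defined).
grad_rel_err <- function(analytic, fd) {
  max(abs(analytic - fd) / pmax(abs(analytic), abs(fd), 1))
}
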