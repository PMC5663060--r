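test_that("AdaGrad arithmetic follows the closed-form update", {
  # first step moves by alpha * sign(g) regardless of |g|
  s1 <- adagrad_step(0, 3, 0, 0.01)
  expect_equal(s1$theta, -0.01)
  expect_equal(s1$state, 9)
  expect_equal(adagrad_step(5, -7, 0, 0.2)$theta, 5 + 0.2)
  # gradients 3 then 4: second step size alpha * 4 / sqrt(9 + 16)
  s2 <- adagrad_step(s1$theta, 4, s1$state, 0.01)
  expect_equal(s1$theta - s2$theta, 0.01 * 4 / 5)
  expect_equal(s2$state, 25)
  # constant gradients: step sizes decay monotonically
  th <- 0; st <- 0; steps <- numeric(10)
  for (i in 1:10) {
    nxt <- adagrad_step(th, 2, st, 0.1)
    steps[i] <- th - nxt$theta
    th <- nxt$theta; st <- nxt$state
  }
  expect_true(all(diff(steps) < 0))
  # zero gradient with empty accumulator: guarded no-op
  s0 <- adagrad_step(1.5, 0, 0, 0.1)
  expect_equal(s0$theta, 1.5)
  expect_equal(s0$state, 0)
  expect_error(adagrad_step(0, 1, 0, 0), "positive")
})

test_that("a small AdaGrad step decreases the loss on a smooth instance", {
  s <- tiny_model_setup(l2 = 0)
  sent <- s$idx[[1]]
  g <- sentence_gradients(sent, s$params, s$config)
  flat <- flatten_params(s$params)
  upd <- adagrad_step(flat, g$flat, numeric(length(flat)), 1e-4)
  after <- sentence_loss(sent, unflatten_params(upd$theta, s$params), s$config)
  expect_lte(after, g$loss)
})

test_that("training overfits a small corpus and is reproducible bit-for-bit", {
  sc <- synth_config(n_sentences = 8L, seed = 5L)
  corpus <- generate_corpus(sc)
  emb <- tempfile()
  generate_embeddings(corpus$vocabulary, dim = 10L, seed = 5L, path = emb)
  cfg <- bioner_config(hidden_dim = 16L, combiner_dim = 12L, char_dim = 8L,
                       char_hidden_dim = 8L, max_epochs = 80L, patience = 80L,
                       seed = 5L)
  fit1 <- bioner(corpus$train, dev = corpus$train, embeddings = emb,
                 config = cfg)
  pred <- predict(fit1, corpus$train)
  expect_equal(score_corpus(corpus$train, pred)$f1, 1.0)
  # same seed and inputs: identical logs and final parameters
  fit2 <- bioner(corpus$train, dev = corpus$train, embeddings = emb,
                 config = cfg)
  expect_identical(fit1$log, fit2$log)
  expect_identical(flatten_params(fit1$params), flatten_params(fit2$params))
  # a different seed leads elsewhere
  cfg3 <- cfg; cfg3$seed <- 6L
  fit3 <- bioner(corpus$train, dev = corpus$train, embeddings = emb,
                 config = cfg3)
  expect_false(identical(fit1$log, fit3$log))
})

test_that("softmax-decoder training never touches the transition matrix", {
  sc <- synth_config(n_sentences = 6L, seed = 9L)
  corpus <- generate_corpus(sc)
  emb <- tempfile()
  generate_embeddings(corpus$vocabulary, dim = 6L, seed = 9L, path = emb)
  cfg <- bioner_config(hidden_dim = 6L, combiner_dim = 5L, char_dim = 4L,
                       char_hidden_dim = 4L, max_epochs = 3L, seed = 9L,
                       decoder = "softmax", early_stop_f1 = 2)
  fit <- bioner(corpus$train, dev = corpus$train, embeddings = emb,
                config = cfg)
  # transitions remain at their initial values: rebuild the same init
  types <- fit$tag_alphabet$types
  wt <- load_word2vec_text(emb, seed = cfg$seed)
  init <- init_model_params(cfg, wt, fit$char_alphabet, fit$tag_alphabet)
  expect_identical(fit$params$trans, init$trans)
})

test_that("strong regularization shrinks the parameter norm epoch over epoch", {
  sc <- synth_config(n_sentences = 5L, seed = 3L)
  corpus <- generate_corpus(sc)
  emb <- tempfile()
  generate_embeddings(corpus$vocabulary, dim = 6L, seed = 3L, path = emb)
  cfg <- bioner_config(hidden_dim = 6L, combiner_dim = 5L, char_dim = 4L,
                       char_hidden_dim = 4L, seed = 3L, l2 = 10,
                       max_epochs = 4L, patience = 4L, early_stop_f1 = 2)
  fit <- bioner(corpus$train, dev = corpus$train, embeddings = emb,
                config = cfg)
  expect_true(all(diff(fit$log$param_norm) < 0))
})

test_that("model archives round-trip and reject damage", {
  sc <- synth_config(n_sentences = 6L, seed = 4L)
  corpus <- generate_corpus(sc)
  emb <- tempfile()
  generate_embeddings(corpus$vocabulary, dim = 6L, seed = 4L, path = emb)
  cfg <- bioner_config(hidden_dim = 6L, combiner_dim = 5L, char_dim = 4L,
                       char_hidden_dim = 4L, max_epochs = 2L, seed = 4L,
                       early_stop_f1 = 2)
  fit <- bioner(corpus$train, dev = corpus$train, embeddings = emb,
                config = cfg)
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(flatten_params(back$params), flatten_params(fit$params))
  expect_identical(back$tag_alphabet, fit$tag_alphabet)
  # decoded tags identical through the round trip
  expect_identical(predict(back, corpus$dev), predict(fit, corpus$dev))
  # truncated archive fails cleanly
  raw <- readBin(path, "raw", file.info(path)$size)
  trunc_path <- tempfile()
  writeBin(raw[1:20], trunc_path)
  expect_error(load_model(trunc_path), "model file|archive")
  # tampered config guard: a model without char parameters refuses +Char
  fit2 <- fit
  fit2$params$char <- NULL
  save_model(fit2, path)
  expect_error(load_model(path), "character parameters")
})
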