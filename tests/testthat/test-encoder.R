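# A naive straight-from-the-formulas reimplementation of the character
# attention (plain loops, no overflow-safe rewrite) used as oracle.
naive_attention <- function(Ec, e_w, att, w = 2L) {
  n <- ncol(Ec); d <- nrow(Ec)
  t_mat <- matrix(0, d, n)
  for (j in seq_len(n)) {
    win <- numeric(0)
    for (o in -w:w) {
      jj <- j + o
      win <- c(win, if (jj >= 1 && jj <= n) Ec[, jj] else numeric(d))
    }
    h_j <- tanh(att$W_c %*% win + att$b_c)
    t_mat[, j] <- exp(att$W_t %*% h_j + att$U_t %*% e_w + att$b_t)
  }
  a <- t_mat / rowSums(t_mat)
  rowSums(a * Ec)
}

test_that("char attention matches the naive formula on random instances", {
  set.seed(31)
  for (rep in 1:20) {
    d <- sample(2:4, 1); n <- sample(1:7, 1); Hc <- sample(2:5, 1)
    dw <- sample(2:5, 1)
    att <- list(W_c = matrix(rnorm(Hc * 5 * d, sd = 0.5), Hc),
                b_c = rnorm(Hc, sd = 0.5),
                W_t = matrix(rnorm(d * Hc, sd = 0.5), d),
                U_t = matrix(rnorm(d * dw, sd = 0.5), d),
                b_t = rnorm(d, sd = 0.5))
    Ec <- matrix(rnorm(d * n), d)
    e_w <- rnorm(dw)
    got <- char_attention(Ec, e_w, att)
    expect_equal(as.vector(got), naive_attention(Ec, e_w, att),
                 tolerance = 1e-8)
    # weights are a per-dimension distribution over characters
    a <- attr(got, "weights")
    expect_true(all(a >= 0))
    expect_equal(rowSums(a), rep(1, d), tolerance = 1e-9)
  }
})

test_that("attention limits: single character and zero parameters", {
  set.seed(32)
  d <- 3L; Hc <- 4L; dw <- 2L
  att <- list(W_c = matrix(rnorm(Hc * 5 * d), Hc), b_c = rnorm(Hc),
              W_t = matrix(rnorm(d * Hc), d), U_t = matrix(rnorm(d * dw), d),
              b_t = rnorm(d))
  # one character: weights are 1 in every dimension, R_c = e_c exactly
  Ec1 <- matrix(rnorm(d), d, 1)
  got <- char_attention(Ec1, rnorm(dw), att)
  expect_equal(as.vector(got), Ec1[, 1])
  expect_equal(attr(got, "weights"), matrix(1, d, 1))
  # zero scoring parameters: uniform weights, mean of character embeddings
  att0 <- att
  att0$W_t[] <- 0; att0$U_t[] <- 0; att0$b_t[] <- 0
  Ec <- matrix(rnorm(d * 5), d)
  got0 <- char_attention(Ec, rnorm(dw), att0)
  expect_equal(as.vector(got0), rowMeans(Ec), tolerance = 1e-12)
  expect_equal(attr(got0, "weights"), matrix(1 / 5, d, 5))
  expect_error(char_attention(matrix(0, d, 0), rnorm(dw), att), "character")
})

test_that("attention survives extreme score magnitudes", {
  d <- 2L; Hc <- 2L
  att <- list(W_c = matrix(0, Hc, 5 * d), b_c = c(500, -500),
              W_t = matrix(c(1000, 0, 0, 1000), d, Hc), U_t = matrix(0, d, 1),
              b_t = c(0, 0))
  Ec <- matrix(c(1, 2, 3, 4), d)
  got <- char_attention(Ec, 0, att)
  expect_true(all(is.finite(got)))
  expect_equal(rowSums(attr(got, "weights")), rep(1, d), tolerance = 1e-9)
})

test_that("word representation concatenates character part first", {
  R_c <- rnorm(30); e_w <- rnorm(50)
  v <- word_representation(R_c, e_w)
  expect_length(v, 80L)
  expect_equal(v[1:30], R_c)
  expect_equal(v[31:80], e_w)
  expect_equal(word_representation(NULL, e_w), e_w)
  expect_equal(word_representation(numeric(30) , e_w)[31:80], e_w)
})

test_that("window features concatenate neighbors with zero padding", {
  set.seed(33)
  R <- matrix(rnorm(4 * 3), 4)
  expect_equal(window_features(R, 0L), R)
  # single token, half-width 2: zero pads on both sides of the center block
  one <- matrix(rnorm(4), 4)
  x <- window_features(one, 2L)
  expect_equal(dim(x), c(20L, 1L))
  expect_equal(x[, 1], c(rep(0, 8), one[, 1], rep(0, 8)))
  # middle position of a 3-token sentence holds R1..R3 contiguously
  x3 <- window_features(R, 2L)
  expect_equal(x3[, 2], c(rep(0, 4), R[, 1], R[, 2], R[, 3], rep(0, 4)))
  expect_error(window_features(R[, 0, drop = FALSE], 2L), "non-empty")
})

test_that("LSTM recurrence: zero parameters, one step, palindrome symmetry", {
  H <- 3L; D <- 2L
  zero <- list(W = matrix(0, 4 * H, D), U = matrix(0, 4 * H, H),
               b = numeric(4 * H))
  X <- matrix(0, D, 4)
  expect_equal(lstm_forward(X, zero), matrix(0, H, 4))
  # one step against hand-composed gate algebra
  set.seed(34)
  p <- list(W = matrix(rnorm(4 * H * D), 4 * H), U = matrix(rnorm(4 * H * H), 4 * H),
            b = rnorm(4 * H))
  x1 <- matrix(rnorm(D), D, 1)
  q <- p$W %*% x1 + p$b
  sig <- function(z) 1 / (1 + exp(-z))
  i_g <- sig(q[1:H]); f_g <- sig(q[H + 1:H]); o_g <- sig(q[2 * H + 1:H])
  g_g <- tanh(q[3 * H + 1:H])
  expect_equal(as.vector(lstm_forward(x1, p)), o_g * tanh(i_g * g_g))
  # palindromic input: the reverse pass mirrors the forward pass
  Xp <- matrix(rnorm(D * 5), D, 5)
  Xp <- Xp[, c(1:5, 4:1)]  # palindromic input of length 9
  expect_equal(lstm_forward(Xp, p, reverse = TRUE),
               lstm_forward(Xp, p)[, ncol(Xp):1])
})

test_that("combiner is a bounded tanh map matching direct evaluation", {
  set.seed(35)
  comb <- list(W = matrix(rnorm(3 * 8), 3), b = rnorm(3))
  hf <- rnorm(4); hb <- rnorm(4)
  got <- combine_hidden(hf, hb, comb)
  expect_equal(got, as.vector(tanh(comb$W %*% c(hf, hb) + comb$b)))
  expect_true(all(abs(got) < 1))
  zero <- list(W = matrix(0, 3, 8), b = numeric(3))
  expect_equal(combine_hidden(hf, hb, zero), rep(0, 3))
  uni <- list(W = matrix(rnorm(3 * 4), 3), b = rnorm(3))
  expect_equal(combine_hidden(hf, NULL, uni),
               as.vector(tanh(uni$W %*% hf + uni$b)))
})

test_that("encode_sentence has the right shape and honors ablation switches", {
  s <- tiny_model_setup()
  h <- encode_sentence(s$idx[[1]], s$params, s$config)
  expect_equal(dim(h), c(s$config$combiner_dim, 3L))
  expect_true(all(is.finite(h)))
  # disabling characters changes the encoding (params built without char)
  s2 <- tiny_model_setup(use_char = FALSE)
  h2 <- encode_sentence(s2$idx[[1]], s2$params, s2$config)
  expect_equal(dim(h2), c(s2$config$combiner_dim, 3L))
  # unidirectional config has no backward parameters at all
  s3 <- tiny_model_setup(bidirectional = FALSE)
  expect_null(s3$params$lstm_b)
  expect_equal(dim(encode_sentence(s3$idx[[1]], s3$params, s3$config)),
               c(s3$config$combiner_dim, 3L))
})

test_that("feature export writes one row per token", {
  s <- tiny_model_setup()
  f <- tempfile()
  export_features(s$idx, s$params, s$config, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 4L)  # 3 + 1 tokens
  expect_equal(ncol(tab), 3L + s$config$combiner_dim)
  expect_equal(tab$token[4], "xx")
})
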