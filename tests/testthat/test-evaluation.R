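mk_sent <- function(tags) list(tokens = sprintf("t%d", seq_along(tags)),
                               tags = tags)

test_that("perfect predictions and the 2/3 arithmetic fixture score exactly", {
  gold <- list(mk_sent(c("B-protein", "E-protein", "O", "S-DNA")))
  expect_equal(score_corpus(gold, gold)$f1, 1.0)
  expect_equal(score_corpus(gold, gold)$fp, 0L)
  expect_equal(score_corpus(gold, gold)$fn, 0L)
  # crafted tp=2, fp=1, fn=1: P = R = F1 = 2/3
  gold2 <- list(
    mk_sent(c("S-protein", "O", "B-DNA", "E-DNA")),
    mk_sent(c("S-DNA", "O", "O"))
  )
  pred2 <- list(
    mk_sent(c("S-protein", "O", "B-DNA", "E-DNA")),
    mk_sent(c("O", "O", "S-DNA"))  # one spurious, one missed
  )
  res <- score_corpus(gold2, pred2)
  expect_equal(res$tp, 2L)
  expect_equal(res$fp, 1L)
  expect_equal(res$fn, 1L)
  expect_equal(res$precision, 2 / 3)
  expect_equal(res$recall, 2 / 3)
  expect_equal(res$f1, 2 / 3)
  # empty-vs-empty degenerates to all-zero counts, zero scores
  none <- list(mk_sent(c("O", "O")))
  z <- score_corpus(none, none)
  expect_equal(c(z$tp, z$precision, z$recall, z$f1), c(0, 0, 0, 0))
})

test_that("a one-token boundary error costs both a FP and a FN", {
  gold <- list(mk_sent(c("B-protein", "I-protein", "E-protein", "O")))
  pred <- list(mk_sent(c("B-protein", "E-protein", "O", "O")))
  res <- score_corpus(gold, pred)
  expect_equal(res$tp, 0L)
  expect_equal(res$fp, 1L)
  expect_equal(res$fn, 1L)
})

test_that("conservation identities hold on randomized corpora", {
  set.seed(71)
  for (rep in 1:15) {
    n <- sample(3:8, 1)
    gold <- lapply(1:n, function(i) {
      mk_sent(iob2_to_bieos(random_iob2(sample(2:10, 1), c("protein", "DNA"))))
    })
    pred <- lapply(gold, function(s) {
      tags <- s$tags
      flip <- runif(length(tags)) < 0.3
      tags[flip] <- sample(c("O", "S-DNA", "B-protein", "E-protein", "I-DNA"),
                           sum(flip), replace = TRUE)
      mk_sent(tags)
    })
    res <- score_corpus(gold, pred)
    n_gold <- sum(sapply(gold, function(s) nrow(bieos_to_spans(s$tags))))
    n_pred <- sum(sapply(pred, function(s) nrow(bieos_to_spans(s$tags))))
    expect_equal(res$tp + res$fn, n_gold)
    expect_equal(res$tp + res$fp, n_pred)
    # swapping roles swaps precision and recall, keeping F1 fixed
    swp <- score_corpus(pred, gold)
    expect_equal(swp$precision, res$recall)
    expect_equal(swp$recall, res$precision)
    expect_equal(swp$f1, res$f1)
    # per-type counts are a partition of the overall counts
    bt <- per_type_breakdown(gold, pred)
    expect_equal(sum(sapply(bt, `[[`, "tp")), res$tp)
    expect_equal(sum(sapply(bt, `[[`, "fp")), res$fp)
    expect_equal(sum(sapply(bt, `[[`, "fn")), res$fn)
  }
})

test_that("alignment errors are reported with the offending sentence", {
  gold <- list(mk_sent(c("O", "O")))
  expect_error(score_corpus(gold, list()), "misaligned")
  expect_error(score_corpus(gold, list(mk_sent("O"))), "sentence 1")
})

test_that("alternative annotations credit secondary boundaries one-to-one", {
  gold <- list(mk_sent(c("B-protein", "I-protein", "E-protein", "O")))
  alts <- list(list(sentence = 1L, type = "protein",
                    spans = matrix(c(0L, 3L, 0L, 2L), ncol = 2, byrow = TRUE,
                                   dimnames = list(NULL, c("start", "end")))))
  # prediction matches the alternative, not the primary: still a TP
  pred <- list(mk_sent(c("B-protein", "E-protein", "O", "O")))
  res <- score_with_alternatives(gold, pred, alts)
  expect_equal(c(res$tp, res$fp, res$fn), c(1L, 0L, 0L))
  expect_equal(res$f1, 1.0)
  # two predictions both matching spans of one gold entity: one TP, one FP
  pred2 <- list(mk_sent(c("B-protein", "E-protein", "S-protein", "O")))
  res2 <- score_with_alternatives(gold, pred2,
    list(list(sentence = 1L, type = "protein",
              spans = matrix(c(0L, 3L, 0L, 2L, 2L, 3L), ncol = 2, byrow = TRUE,
                             dimnames = list(NULL, c("start", "end"))))))
  expect_equal(c(res2$tp, res2$fp, res2$fn), c(1L, 1L, 0L))
  # the wrong type never matches
  predt <- list(mk_sent(c("B-DNA", "E-DNA", "O", "O")))
  rest <- score_with_alternatives(gold, predt, alts)
  expect_equal(rest$tp, 0L)
  # empty alternative sets reduce exactly to plain scoring
  same <- score_with_alternatives(gold, pred, list())
  plain <- score_corpus(gold, pred)
  expect_equal(same$tp, plain$tp)
  expect_equal(same$f1, plain$f1)
  # out-of-range alternative span is rejected
  bad <- list(list(sentence = 1L, type = "protein",
                   spans = matrix(c(0L, 3L, 0L, 9L), ncol = 2, byrow = TRUE,
                                  dimnames = list(NULL, c("start", "end")))))
  expect_error(score_with_alternatives(gold, pred, bad), "length")
})

test_that("alternatives never reduce the credit of plain scoring", {
  set.seed(72)
  for (rep in 1:10) {
    gold <- lapply(1:4, function(i) {
      mk_sent(iob2_to_bieos(random_iob2(8, c("protein", "DNA"))))
    })
    pred <- lapply(gold, function(s) {
      tags <- s$tags
      if (runif(1) < 0.7) tags <- sample(tags)  # scramble some sentences
      mk_sent(bieos_to_spans(tags) |> spans_to_bieos(length(tags)))
    })
    alts <- generate_alternatives(gold, rate = 0.5, seed = rep)
    plain <- score_corpus(gold, pred)
    cred <- score_with_alternatives(gold, pred, alts)
    expect_gte(cred$tp, plain$tp)
  }
})

test_that("per-type breakdown books type confusions on both sides", {
  gold <- list(mk_sent(c("B-protein", "E-protein", "O")))
  pred <- list(mk_sent(c("B-DNA", "E-DNA", "O")))
  bt <- per_type_breakdown(gold, pred)
  expect_equal(bt$protein$fn, 1L)
  expect_equal(bt$protein$fp, 0L)
  expect_equal(bt$DNA$fp, 1L)
  expect_equal(bt$DNA$fn, 0L)
  # single-type corpus: breakdown equals the overall result
  g1 <- list(mk_sent(c("S-DNA", "O")))
  bt1 <- per_type_breakdown(g1, g1)
  expect_length(bt1, 1L)
  expect_equal(bt1$DNA$f1, score_corpus(g1, g1)$f1)
})

test_that("reports render counts and rates in both formats", {
  gold <- list(mk_sent(c("S-protein", "O", "S-DNA")))
  pred <- list(mk_sent(c("S-protein", "O", "O")))
  overall <- score_corpus(gold, pred)
  txt <- format_eval_report(overall, per_type_breakdown(gold, pred))
  expect_length(txt, 3L)
  expect_match(txt[1], "overall")
  tsv <- format_eval_report(overall, format = "tsv")
  expect_equal(strsplit(tsv[1], "\t")[[1]][1], "scope")
  expect_equal(strsplit(tsv[2], "\t")[[1]][2], "1")  # tp
})
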