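test_that("read_conll parses sentences, columns and boundary cases", {
  f <- tempfile()
  writeLines(c("IL-2\tB-protein", "gene\tE-protein", "binds\tO", "",
               "DNA\tS-DNA", "x\tO"), f)
  sents <- read_conll(f)
  expect_length(sents, 2L)
  expect_equal(lengths(lapply(sents, `[[`, "tokens")), c(3L, 2L))
  expect_equal(sents[[1]]$tags, c("B-protein", "E-protein", "O"))
  # no trailing blank line: last sentence still emitted
  expect_equal(sents[[2]]$tokens, c("DNA", "x"))
  # malformed line reports its number
  writeLines(c("tok\tO", "lonely"), f)
  expect_error(read_conll(f), "line 2")
  expect_error(read_conll(f, token_column = 0), "positive")
})

test_that("read/write round trip is the identity on randomized corpora", {
  set.seed(404)
  for (rep in 1:5) {
    sents <- lapply(seq_len(sample(2:6, 1)), function(i) {
      n <- sample(1:8, 1)
      list(tokens = replicate(n, paste(sample(c(letters, "-", "1"), 5,
                                              replace = TRUE), collapse = "")),
           tags = iob2_to_bieos(random_iob2(n, c("protein", "DNA"))))
    })
    f <- tempfile()
    write_conll(sents, f)
    back <- read_conll(f)
    expect_equal(back, sents)
  }
})

test_that("IOB2 to BIEOS conversion rewrites boundaries and rejects invalid input", {
  expect_equal(iob2_to_bieos(c("B-protein", "I-protein", "O")),
               c("B-protein", "E-protein", "O"))
  expect_equal(iob2_to_bieos("B-DNA"), "S-DNA")
  expect_equal(iob2_to_bieos(character(0)), character(0))
  expect_error(iob2_to_bieos(c("O", "I-protein")), "position 2")
  expect_error(iob2_to_bieos(c("B-DNA", "I-protein")), "position 2")
})

test_that("scheme conversion preserves span sets on random valid sequences", {
  set.seed(11)
  for (rep in 1:40) {
    tags <- random_iob2(sample(1:12, 1), c("protein", "DNA", "RNA"))
    out <- iob2_to_bieos(tags)
    expect_true(isTRUE(is_bieos_valid(out)))
    expect_equal(bieos_to_spans(out), iob2_to_spans(tags))
  }
})

test_that("span extraction handles valid input, empty input, and repairs", {
  expect_equal(
    bieos_to_spans(c("B-protein", "E-protein", "O", "S-DNA")),
    data.frame(start = c(0L, 3L), end = c(2L, 4L),
               type = c("protein", "DNA"), stringsAsFactors = FALSE))
  expect_equal(nrow(bieos_to_spans(c("O", "O", "O"))), 0L)
  # stray I opens a span as if B
  expect_equal(bieos_to_spans(c("I-protein", "E-protein")),
               data.frame(start = 0L, end = 2L, type = "protein",
                          stringsAsFactors = FALSE))
  # incompatible continuation closes at the boundary
  expect_equal(bieos_to_spans(c("B-protein", "B-DNA"))$start, c(0L, 1L))
  expect_equal(bieos_to_spans(c("B-protein", "O"))$end, 1L)
  # unterminated run closes at sentence end
  expect_equal(bieos_to_spans(c("O", "B-DNA", "I-DNA"))$end, 3L)
  # stray E alone is a single-token span
  expect_equal(bieos_to_spans("E-DNA"),
               data.frame(start = 0L, end = 1L, type = "DNA",
                          stringsAsFactors = FALSE))
})

test_that("token normalization lowercases, maps digit runs, and is idempotent", {
  expect_equal(normalize_token("Characterization"), "characterization")
  expect_equal(normalize_token("1234"), "NUM")
  expect_equal(normalize_token("IL-2"), "il-NUM")
  expect_equal(normalize_token("IL-2", digits = "whole_token"), "il-2")
  expect_equal(normalize_token("1234", digits = "whole_token"), "NUM")
  set.seed(5)
  toks <- c("Abc", "X9Y8", "NUM", "p53", "alpha-1,2", "IL2R")
  for (mode in c("digit_run", "whole_token")) {
    once <- normalize_token(toks, digits = mode)
    expect_equal(normalize_token(once, digits = mode), once)
  }
})

test_that("indexing maps vocabulary hits, unknowns and tags correctly", {
  s <- tiny_model_setup()
  idx <- s$idx
  # in-vocabulary normalized token resolves to its own row
  norm <- normalize_token("de")
  expect_equal(idx[[1]]$word_ids[2], unname(s$params$word$index[norm]))
  # unseen token maps to UNKNOWN
  oov <- index_corpus(list(list(tokens = "zzzz", tags = "O")),
                      s$params$word, s$char_alphabet, s$tag_alphabet)
  expect_equal(oov[[1]]$word_ids, s$params$word$unknown_id)
  # character ids come from the raw surface (case preserved)
  expect_equal(length(idx[[1]]$char_ids[[1]]), nchar("Abc1"))
  # unknown tag rejected
  expect_error(
    index_corpus(list(list(tokens = "a", tags = "S-cellline")),
                 s$params$word, s$char_alphabet, s$tag_alphabet),
    "tag")
  expect_equal(index_corpus(list(), s$params$word, s$char_alphabet,
                            s$tag_alphabet), list())
})

test_that("alternatives sidecar round-trips through its file format", {
  alts <- list(
    list(sentence = 1L, type = "protein",
         spans = matrix(c(0L, 2L, 0L, 3L), ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("start", "end")))),
    list(sentence = 3L, type = "DNA",
         spans = matrix(c(1L, 2L), ncol = 2,
                        dimnames = list(NULL, c("start", "end")))))
  f <- tempfile()
  write_alternatives(alts, f)
  back <- read_alternatives(f)
  expect_equal(back, alts)
  writeLines("1\tprotein\t2,1", f)
  expect_error(read_alternatives(f), "span")
})
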