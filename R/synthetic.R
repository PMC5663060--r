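# Seeded synthetic corpora, embeddings and alternative annotations.
#
# The generators emulate the *structure* that biomedical NER models
# exploit -- multi-token entities of several types with a realistic span
# length profile (about 40% single-token mentions and 15% longer than
# three tokens), morphological cues inside entity tokens, and lexical
# trigger words in the context -- without using any real gene names.
# Tokens are synthetic strings; all randomness is a pure function of the
# configuration and seed.

#' Synthetic corpus configuration
#'
#' @param n_sentences number of training sentences (the dev and test
#'   splits are sized as fractions of this).
#' @param entity_types entity-type labels.
#' @param entity_length_probs named numeric vector of span-length
#'   probabilities (names = lengths); the default puts 40% of mentions at
#'   one token, 45% at two or three, 15% at four or five.
#' @param morphology_cue_rate probability that an entity head token
#'   carries its type-specific suffix.
#' @param context_cue_rate probability that a type-specific trigger word
#'   immediately precedes an entity.
#' @param digit_rate probability that a non-head entity token carries a
#'   numeric qualifier (exercising digit normalization).
#' @param n_fillers,n_stems,n_triggers vocabulary pool sizes (stems and
#'   triggers are per entity type).
#' @param dev_frac,test_frac relative sizes of the dev and test splits.
#' @param variant `"standard"`; `"transition"` builds a corpus whose
#'   entity types are reliably recoverable only through tag-bigram
#'   structure: a span's type is set by its first token while interior
#'   tokens carry independently drawn (often conflicting) surface class
#'   evidence; `"morphology"` builds one whose entity tokens are all out
#'   of the embedding vocabulary and typed only by their character
#'   suffix.
#' @param ambiguity_rate (transition variant) probability that an
#'   interior entity token draws its surface class at random instead of
#'   matching the span's type, planting conflicting local type evidence
#'   inside spans.
#' @param seed RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_sentences = 2000L,
                         entity_types = c("protein", "DNA"),
                         entity_length_probs = c(`1` = 0.40, `2` = 0.225,
                                                 `3` = 0.225, `4` = 0.10,
                                                 `5` = 0.05),
                         morphology_cue_rate = 0.9,
                         context_cue_rate = 0.7,
                         digit_rate = 0.2,
                         n_fillers = 120L, n_stems = 60L, n_triggers = 6L,
                         dev_frac = 0.1, test_frac = 0.2,
                         variant = c("standard", "transition", "morphology"),
                         ambiguity_rate = 0.8,
                         seed = 1L) {
  variant <- match.arg(variant)
  if (abs(sum(entity_length_probs) - 1) > 1e-8) {
    stop_config("entity_length_probs must sum to 1")
  }
  probs_rates <- c(morphology_cue_rate, context_cue_rate, digit_rate,
                   ambiguity_rate, entity_length_probs)
  if (any(probs_rates < 0 | probs_rates > 1)) {
    stop_config("probabilities must lie in [0, 1]")
  }
  if (max(as.integer(names(entity_length_probs))) > 5L) {
    stop_config("entity lengths are truncated at 5 tokens")
  }
  structure(
    list(n_sentences = as.integer(n_sentences), entity_types = entity_types,
         entity_length_probs = entity_length_probs,
         morphology_cue_rate = morphology_cue_rate,
         context_cue_rate = context_cue_rate, digit_rate = digit_rate,
         n_fillers = as.integer(n_fillers), n_stems = as.integer(n_stems),
         n_triggers = as.integer(n_triggers), dev_frac = dev_frac,
         test_frac = test_frac, variant = variant,
         ambiguity_rate = ambiguity_rate, seed = as.integer(seed)),
    class = "synth_config")
}

# Two-letter token indices: pool tokens are digit-free so that the NUM
# normalization rule leaves them distinct (digits appear only in the
# intended numeric qualifiers).
letter_ids <- function(n) {
  v <- as.vector(t(outer(letters, letters, paste0)))
  if (n > length(v)) stop_config("pool size %d exceeds %d", n, length(v))
  v[seq_len(n)]
}

synth_pools <- function(config) {
  nt <- length(config$entity_types)
  list(
    fillers = paste0("fil", letter_ids(config$n_fillers)),
    ambiguous = paste0("amb", letter_ids(max(20L, config$n_fillers %/% 4L))),
    triggers = lapply(seq_len(nt), function(k) {
      paste0("tg", letters[k], letter_ids(config$n_triggers))
    }),
    stems = lapply(seq_len(nt), function(k) {
      paste0("st", letters[k], letter_ids(config$n_stems))
    }),
    shared_stems = paste0("sha", letter_ids(config$n_stems)),
    class_stems = lapply(seq_len(max(2L, nt)), function(k) {
      paste0("q", letters[k], letter_ids(config$n_stems))
    }),
    suffixes = paste0("x", letters[seq_len(nt)], "q")
  )
}

# Zipf-ish sampling: frequent pool heads dominate, as in natural text.
zipf_sample <- function(pool, n) {
  if (n == 0L) return(character(0))
  w <- 1 / seq_along(pool)
  pool[sample.int(length(pool), n, replace = TRUE, prob = w / sum(w))]
}

synth_sentence <- function(config, pools) {
  nt <- length(config$entity_types)
  n_ent <- 1L + stats::rbinom(1L, 2L, 0.45)
  toks <- character(0); spans <- list()
  add_fillers <- function(min_n = 0L) {
    nf <- min_n + stats::rpois(1L, 1.2)
    toks <<- c(toks, zipf_sample(pools$fillers, nf))
  }
  add_fillers()
  for (e in seq_len(n_ent)) {
    k <- sample.int(nt, 1L)
    ty <- config$entity_types[k]
    if (config$variant == "transition") {
      k <- sample(1:2, 1L)
      len <- sample(2:3, 1L)
      if (stats::runif(1) < config$ambiguity_rate) {
        # type-ambiguous entity: the gold type is drawn at random and is
        # unobservable, while each interior token carries strong but
        # independently drawn (hence conflicting) class evidence.
        # Independent per-token decisions then mix types within the span
        # (invalid, fragmenting on repair); a joint decode must commit to
        # one type for the whole span via tag bigrams.
        ty <- config$entity_types[sample(1:2, 1L)]
        len <- sample(3:4, 1L)
        ent <- c(sample(pools$ambiguous, 1L),
                 vapply(sample(1:2, len - 1L, replace = TRUE),
                        function(cj) sample(pools$class_stems[[cj]], 1L),
                        character(1)))
      } else {
        ty <- config$entity_types[k]
        ent <- sample(pools$class_stems[[k]], len, replace = FALSE)
      }
    } else if (config$variant == "morphology") {
      len <- sample(as.integer(names(config$entity_length_probs)), 1L,
                    prob = config$entity_length_probs)
      ent <- paste0(sample(pools$shared_stems, len, replace = FALSE),
                    pools$suffixes[k])
    } else {
      len <- sample(as.integer(names(config$entity_length_probs)), 1L,
                    prob = config$entity_length_probs)
      ent <- sample(pools$stems[[k]], len, replace = FALSE)
      # head token (final position) carries the type suffix
      if (stats::runif(1) < config$morphology_cue_rate) {
        ent[len] <- paste0(ent[len], pools$suffixes[k])
      }
      if (len > 1L) {
        dig <- stats::runif(len - 1L) < config$digit_rate
        ent[which(dig)] <- paste0(ent[which(dig)], "-",
                                  sample.int(99L, sum(dig), replace = TRUE))
      }
      if (stats::runif(1) < config$context_cue_rate) {
        toks <- c(toks, sample(pools$triggers[[k]], 1L))
      }
    }
    spans[[length(spans) + 1L]] <-
      data.frame(start = length(toks), end = length(toks) + len, type = ty,
                 stringsAsFactors = FALSE)
    toks <- c(toks, ent)
    add_fillers(min_n = 1L)  # at least one filler keeps entities separated
  }
  spans <- do.call(rbind, spans)
  list(tokens = toks, tags = spans_to_bieos(spans, length(toks)))
}

#' Generate a synthetic tagged corpus
#'
#' Produces disjoint train/dev/test splits of trigger/filler/entity token
#' sequences with BIEOS-valid tags by construction. Byte-identical across
#' runs for a fixed configuration.
#'
#' @param config a [synth_config()].
#' @return list with `train`, `dev`, `test` (each a list of sentences),
#'   `vocabulary` (the normalized token set intended for the embedding
#'   file -- entity tokens are excluded under the morphology variant so
#'   that they map to `UNKNOWN`), and the `config`.
#' @export
generate_corpus <- function(config = synth_config()) {
  pools <- synth_pools(config)
  max_len <- if (config$variant == "transition") 3L else
    max(as.integer(names(config$entity_length_probs)))
  if (max_len > config$n_stems) {
    stop_config("entity length %d exceeds the stem pool size %d",
                max_len, config$n_stems)
  }
  n_dev <- max(1L, round(config$dev_frac * config$n_sentences))
  n_test <- max(1L, round(config$test_frac * config$n_sentences))
  with_seed(config$seed, {
    gen_split <- function(n) {
      lapply(seq_len(n), function(i) synth_sentence(config, pools))
    }
    splits <- list(train = gen_split(config$n_sentences),
                   dev = gen_split(n_dev), test = gen_split(n_test))
    vocab <- corpus_vocabulary(c(splits$train, splits$dev, splits$test))
    if (config$variant == "morphology") {
      # entity tokens are built on the shared "sh" stems; dropping them
      # from the vocabulary forces every entity token to UNKNOWN
      vocab <- vocab[!startsWith(vocab, "sh")]
    }
    c(splits, list(vocabulary = vocab, config = config))
  })
}

#' Generate a synthetic word2vec embedding file
#'
#' Writes one vector per token in word2vec text format. With
#' `cue_structure = TRUE`, tokens sharing a morpheme cluster (by default,
#' their first three characters, which groups the generator's pools by
#' function and entity type) share a latent direction, so within-cluster
#' cosine similarity exceeds between-cluster similarity -- emulating the
#' informativeness of pre-trained embeddings.
#'
#' @param vocab character vector of tokens.
#' @param dim embedding dimension.
#' @param cue_structure correlate vectors within morpheme clusters?
#' @param seed RNG seed.
#' @param path output file path.
#' @param clusters optional explicit cluster labels (named by token or
#'   positional); default clusters by `substr(token, 1, 3)`.
#' @return `path`, invisibly.
#' @export
generate_embeddings <- function(vocab, dim = 25L, cue_structure = TRUE,
                                seed = 1L, path, clusters = NULL) {
  if (!is_count(dim) || dim < 1L) stop_config("dim must be a positive integer")
  if (anyDuplicated(vocab)) stop_config("vocab must not contain duplicates")
  if (is.null(clusters)) clusters <- substr(vocab, 1L, 3L)
  mat <- with_seed(seed, {
    noise <- matrix(stats::rnorm(length(vocab) * dim, sd = 0.3),
                    nrow = length(vocab))
    if (cue_structure) {
      cl <- factor(clusters)
      centers <- matrix(stats::rnorm(nlevels(cl) * dim, sd = 0.6),
                        nrow = nlevels(cl))
      centers[as.integer(cl), , drop = FALSE] + noise
    } else noise
  })
  write_word2vec_text(vocab, mat, path)
}

#' Generate alternative-annotation records for a corpus
#'
#' For a `rate` fraction of gold entities, adds one alternative span of
#' the same type that is one token shorter or one token longer than the
#' primary span (when such a span fits the sentence); emulating
#' gene-mention style secondary gold boundaries.
#'
#' @param sentences list of gold sentences.
#' @param rate probability that an entity receives an alternative.
#' @param seed RNG seed.
#' @return list of records as accepted by [score_with_alternatives()] and
#'   [write_alternatives()].
#' @export
generate_alternatives <- function(sentences, rate, seed = 1L) {
  if (rate < 0 || rate > 1) stop_config("rate must lie in [0, 1]")
  with_seed(seed, {
    out <- list()
    for (i in seq_along(sentences)) {
      sp <- bieos_to_spans(sentences[[i]]$tags)
      len <- length(sentences[[i]]$tags)
      for (r in seq_len(nrow(sp))) {
        if (stats::runif(1) >= rate) next
        s <- sp$start[r]; e <- sp$end[r]
        cands <- list()
        if (e - s >= 2L) cands <- c(cands, list(c(s + 1L, e)), list(c(s, e - 1L)))
        if (s > 0L) cands <- c(cands, list(c(s - 1L, e)))
        if (e < len) cands <- c(cands, list(c(s, e + 1L)))
        if (!length(cands)) next
        alt <- cands[[sample.int(length(cands), 1L)]]
        out[[length(out) + 1L]] <- list(
          sentence = i, type = sp$type[r],
          spans = matrix(c(s, e, alt[1L], alt[2L]), ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("start", "end"))))
      }
    }
    out
  })
}
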