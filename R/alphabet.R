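# Character alphabet construction and corpus indexing.

#' Build a character alphabet from a corpus
#'
#' Characters are taken from the raw token surface forms (case and digits
#' intact); an unknown-character id covers characters unseen at training
#' time. Alphabets are frozen before the test split is indexed.
#'
#' @param sentences list of sentences (`tokens`/`tags`).
#' @return a list with `chars` (ordered character vector), `index` (named
#'   integer map), and `unknown_id`.
#' @export
build_char_alphabet <- function(sentences) {
  chars <- sort(unique(unlist(
    lapply(sentences, function(s) strsplit(s$tokens, "", fixed = TRUE)),
    use.names = FALSE)))
  structure(
    list(chars = chars,
         index = stats::setNames(seq_along(chars), chars),
         unknown_id = length(chars) + 1L,
         size = length(chars)),
    class = "char_alphabet"
  )
}

char_ids_for_token <- function(alphabet, token) {
  cs <- strsplit(token, "", fixed = TRUE)[[1]]
  ids <- alphabet$index[cs]
  ids[is.na(ids)] <- alphabet$unknown_id
  unname(ids)
}

#' Index a corpus against model alphabets
#'
#' Attaches, per token, the word-embedding row id of its normalized form
#' (the `UNKNOWN` row when absent from the embedding vocabulary),
#' character ids derived from the raw surface form, and the tag id.
#'
#' @param sentences list of sentences.
#' @param word_table word `embedding_table`.
#' @param char_alphabet a `char_alphabet` from [build_char_alphabet()].
#' @param tag_alphabet a [tag_alphabet()].
#' @param digits digit convention passed to [normalize_token()].
#' @param strict if `TRUE`, a tag absent from `tag_alphabet` (e.g. a test
#'   split tag unseen in training) is an error; predictions are indexed
#'   with `strict = TRUE` as well since decoders only emit alphabet tags.
#' @return list of indexed sentences, each adding `word_ids`, `char_ids`
#'   (list of integer vectors) and `tag_ids` to `tokens`/`tags`.
#' @export
index_corpus <- function(sentences, word_table, char_alphabet, tag_alphabet,
                         digits = "digit_run", strict = TRUE) {
  lapply(sentences, function(s) {
    norm <- normalize_token(s$tokens, digits = digits)
    tag_ids <- tag_alphabet$index[s$tags]
    if (strict && anyNA(tag_ids)) {
      bad <- which(is.na(tag_ids))[1]
      stop_config("tag '%s' not in the training tag alphabet", s$tags[bad])
    }
    list(tokens = s$tokens,
         tags = s$tags,
         normalized = norm,
         word_ids = embedding_ids(word_table, norm),
         char_ids = lapply(s$tokens, char_ids_for_token,
                           alphabet = char_alphabet),
         tag_ids = unname(tag_ids))
  })
}

#' Collect the normalized vocabulary of a corpus
#'
#' @param sentences list of sentences.
#' @param digits digit convention passed to [normalize_token()].
#' @return character vector of distinct normalized tokens, in first-seen
#'   order.
#' @export
corpus_vocabulary <- function(sentences, digits = "digit_run") {
  unique(unlist(lapply(sentences, function(s) {
    normalize_token(s$tokens, digits = digits)
  }), use.names = FALSE))
}
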