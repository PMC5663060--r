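# CoNLL-style corpus I/O: two(+)-column whitespace-delimited files with
# blank-line sentence separators, plus the alternative-annotation sidecar.

#' Read a CoNLL-style tagged corpus
#'
#' Parses a UTF-8 file of whitespace-delimited columns, one token per line,
#' with blank lines separating sentences. Tags are returned verbatim;
#' tag-scheme conversion is a separate step ([iob2_to_bieos()]).
#'
#' @param path path to the corpus file.
#' @param token_column 1-based column index holding the token surface form.
#' @param tag_column 1-based column index holding the tag; `NA` to read an
#'   untagged file (all tags set to `"O"`).
#' @return a list of sentences, each `list(tokens = <chr>, tags = <chr>)`.
#'   A file with no trailing blank line still yields its last sentence.
#' @examples
#' f <- tempfile()
#' writeLines(c("IL-2\tB-protein", "gene\tO", "", "binds\tO"), f)
#' length(read_conll(f))
#' @export
read_conll <- function(path, token_column = 1L, tag_column = 2L) {
  if (!file.exists(path)) stop_config("corpus file not found: %s", path)
  if (!is_count(token_column) || token_column < 1L) {
    stop_config("token_column must be a positive integer")
  }
  untagged <- is.na(tag_column)
  if (!untagged && (!is_count(tag_column) || tag_column < 1L)) {
    stop_config("tag_column must be a positive integer or NA")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  toks <- character(0); tags <- character(0)
  flush_sentence <- function() {
    if (length(toks)) {
      sentences[[length(sentences) + 1L]] <<- list(tokens = toks, tags = tags)
      toks <<- character(0); tags <<- character(0)
    }
  }
  need <- max(token_column, if (untagged) 0L else tag_column)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) { flush_sentence(); next }
    fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(fields) < need) {
      stop_config("malformed line %d in %s: %d field(s), need >= %d",
                  i, path, length(fields), need)
    }
    toks <- c(toks, fields[[token_column]])
    tags <- c(tags, if (untagged) "O" else fields[[tag_column]])
  }
  flush_sentence()
  sentences
}

#' Write a corpus in CoNLL two-column format
#'
#' @param sentences list of sentences as returned by [read_conll()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(sentences, path) {
  out <- character(0)
  for (s in sentences) {
    out <- c(out, paste(s$tokens, s$tags, sep = "\t"), "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read an alternative-annotation sidecar file
#'
#' Gene-mention style evaluation accepts secondary gold boundaries: a
#' prediction matching any listed alternative of a gold entity also counts
#' as a true positive. The sidecar is a tab-separated file with one record
#' per gold entity:
#' `sentence<TAB>type<TAB>start,end[;start,end...]`
#' where `sentence` is the 1-based sentence index and spans are 0-based
#' half-open token intervals, the first span being the primary annotation.
#'
#' @param path sidecar file path.
#' @return a list with one element per record:
#'   `list(sentence, type, spans)` where `spans` is a 2-column matrix of
#'   `(start, end)` rows, row 1 the primary span.
#' @export
read_alternatives <- function(path) {
  if (!file.exists(path)) stop_config("alternatives file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      stop_config("malformed alternatives line %d: need 3 tab-separated fields", i)
    }
    span_txt <- strsplit(fields[[3]], ";", fixed = TRUE)[[1]]
    spans <- do.call(rbind, lapply(span_txt, function(sp) {
      se <- suppressWarnings(as.integer(strsplit(sp, ",", fixed = TRUE)[[1]]))
      if (length(se) != 2L || anyNA(se) || se[1] < 0L || se[2] <= se[1]) {
        stop_config("malformed span '%s' on alternatives line %d", sp, i)
      }
      se
    }))
    colnames(spans) <- c("start", "end")
    list(sentence = as.integer(fields[[1]]), type = fields[[2]], spans = spans)
  })
}

#' Write an alternative-annotation sidecar file
#'
#' @param alternatives list of records as returned by [read_alternatives()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alternatives <- function(alternatives, path) {
  lines <- vapply(alternatives, function(a) {
    spans <- paste(apply(a$spans, 1L, paste, collapse = ","), collapse = ";")
    paste(a$sentence, a$type, spans, sep = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
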