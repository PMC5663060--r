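# Embedding tables and parameter initialization schemes.
#
# Word vectors arrive in word2vec text format; character embeddings are
# drawn uniform in [0,1); all dense-layer weights (and biases) are drawn
# uniform in the Glorot bound +/- sqrt(6 / (nrows + ncols)).

UNKNOWN_TOKEN <- "UNKNOWN"
PAD_TOKEN <- "<PAD>"

new_embedding_table <- function(tokens, matrix, trainable) {
  stopifnot(length(tokens) == nrow(matrix))
  structure(
    list(tokens = tokens,
         index = stats::setNames(seq_along(tokens), tokens),
         matrix = matrix,
         dim = ncol(matrix),
         trainable = trainable,
         unknown_id = match(UNKNOWN_TOKEN, tokens),
         pad_id = match(PAD_TOKEN, tokens)),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding table: %d rows x %d dims (%strainable)\n",
              nrow(x$matrix), x$dim, if (x$trainable) "" else "not "))
  invisible(x)
}

#' Look up embedding row ids for tokens
#'
#' Out-of-vocabulary tokens map to the `UNKNOWN` row.
#'
#' @param table an `embedding_table`.
#' @param tokens character vector (already normalized for word tables).
#' @return integer vector of row ids.
#' @export
embedding_ids <- function(table, tokens) {
  ids <- table$index[tokens]
  ids[is.na(ids)] <- table$unknown_id
  unname(ids)
}

#' Load word embeddings from a word2vec text file
#'
#' Reads the token-per-line text dialect (`token v1 v2 ... vd`), with or
#' without the optional `count dim` header line. Vocabulary order is
#' preserved; an `UNKNOWN` row (uniform in the Glorot bound for the matrix
#' shape) and an all-zero `<PAD>` row are appended. The binary word2vec
#' format is not parsed; convert it to text first (e.g. with gensim's
#' `KeyedVectors.save_word2vec_format(..., binary=False)`).
#'
#' @param path embeddings file path.
#' @param expected_dim if given, the file's dimension must equal it.
#' @param trainable whether the vectors are fine-tuned during training.
#' @param seed seed for the `UNKNOWN` row initialization.
#' @return an `embedding_table`.
#' @export
load_word2vec_text <- function(path, expected_dim = NULL, trainable = TRUE,
                               seed = 1L) {
  if (!file.exists(path)) stop_config("embeddings file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_config("empty embeddings file: %s", path)
  first <- strsplit(trimws(lines[[1]]), "[ \t]+")[[1]]
  has_header <- length(first) == 2L &&
    !anyNA(suppressWarnings(as.integer(first)))
  if (has_header) lines <- lines[-1L]
  if (!length(lines)) stop_config("embeddings file has a header but no vectors: %s", path)
  parsed <- strsplit(trimws(lines), "[ \t]+")
  d <- length(parsed[[1]]) - 1L
  if (d < 1L) stop_config("malformed embeddings line 1: no vector values")
  tokens <- character(length(parsed))
  mat <- matrix(0, nrow = length(parsed) + 2L, ncol = d)
  for (i in seq_along(parsed)) {
    f <- parsed[[i]]
    if (length(f) != d + 1L) {
      stop_config("inconsistent vector length on line %d (%d values, expected %d)",
                  i + has_header, length(f) - 1L, d)
    }
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) stop_config("non-numeric vector value on line %d", i + has_header)
    tokens[i] <- f[[1L]]
    mat[i, ] <- v
  }
  if (!is.null(expected_dim) && d != expected_dim) {
    stop_config("embedding dimension %d does not match expected %d", d, expected_dim)
  }
  n <- length(tokens)
  # UNKNOWN row: Glorot-bounded uniform for this matrix's shape; PAD: zeros.
  mat[n + 1L, ] <- with_seed(seed, {
    b <- sqrt(6 / (nrow(mat) + d))
    stats::runif(d, -b, b)
  })
  new_embedding_table(c(tokens, UNKNOWN_TOKEN, PAD_TOKEN), mat, trainable)
}

#' Write an embedding table or matrix in word2vec text format
#'
#' @param tokens character vector of tokens.
#' @param matrix numeric matrix, one row per token.
#' @param path output path.
#' @param header write the `count dim` header line?
#' @return `path`, invisibly.
#' @export
write_word2vec_text <- function(tokens, matrix, path, header = TRUE) {
  stopifnot(length(tokens) == nrow(matrix))
  rows <- vapply(seq_along(tokens), function(i) {
    paste(c(tokens[i], format(matrix[i, ], scientific = FALSE, trim = TRUE,
                              digits = 8)), collapse = " ")
  }, character(1))
  if (header) rows <- c(paste(length(tokens), ncol(matrix)), rows)
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Initialize character embeddings
#'
#' Character vectors are drawn uniform in `[0, 1)` and are always
#' trainable; the table has one row per alphabet character plus an
#' unknown-character row.
#'
#' @param alphabet_size number of distinct characters (excluding unknown).
#' @param dim embedding dimension (default 30).
#' @param seed RNG seed; the draw is a pure function of shape and seed.
#' @return an `embedding_table` with `alphabet_size + 1` rows.
#' @export
init_char_embeddings <- function(alphabet_size, dim = 30L, seed = 1L) {
  if (!is_count(alphabet_size) || alphabet_size < 1L) {
    stop_config("alphabet_size must be a positive integer")
  }
  if (!is_count(dim) || dim < 1L) stop_config("dim must be a positive integer")
  n <- alphabet_size + 1L  # + unknown character
  mat <- with_seed(seed, matrix(stats::runif(n * dim), nrow = n, ncol = dim))
  tokens <- c(sprintf("char%04d", seq_len(alphabet_size)), UNKNOWN_TOKEN)
  tab <- new_embedding_table(tokens, mat, trainable = TRUE)
  tab$pad_id <- NA_integer_  # character windows pad with the zero vector
  tab
}

#' Glorot-uniform layer initialization
#'
#' Draws an `n_rows x n_cols` matrix with entries uniform in
#' `[-sqrt(6/(n_rows+n_cols)), +sqrt(6/(n_rows+n_cols))]`. Bias vectors use
#' the same rule with the shape of their owning weight matrix.
#'
#' @param n_rows,n_cols matrix shape.
#' @param seed RNG seed; the draw is a pure function of shape and seed.
#' @return numeric matrix.
#' @export
init_layer_weights <- function(n_rows, n_cols, seed = 1L) {
  if (!is_count(n_rows) || n_rows < 1L || !is_count(n_cols) || n_cols < 1L) {
    stop_config("layer dimensions must be positive integers")
  }
  b <- sqrt(6 / (n_rows + n_cols))
  with_seed(seed, matrix(stats::runif(n_rows * n_cols, -b, b),
                         nrow = n_rows, ncol = n_cols))
}
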