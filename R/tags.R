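# Tag schemes: BIEOS alphabet construction, validation, IOB2 conversion,
# and span extraction with deterministic repair of invalid predictions.

#' Construct a BIEOS tag alphabet
#'
#' Builds the full tag inventory `{O} U {B-,I-,E-,S- x entity_types}` with a
#' fixed, reproducible label order: `O` first, then the four positional
#' prefixes for each entity type in the order given.
#'
#' @param entity_types character vector of entity-type names
#'   (e.g. `c("protein", "DNA")`).
#' @return an object of class `tag_alphabet`: a list with `labels` (ordered
#'   character vector), `types`, and `index` (named integer map label -> id).
#' @examples
#' ab <- tag_alphabet(c("protein", "DNA"))
#' ab$labels
#' @export
tag_alphabet <- function(entity_types) {
  entity_types <- as.character(entity_types)
  if (length(entity_types) == 0L || anyDuplicated(entity_types)) {
    stop_config("entity_types must be a non-empty set of distinct type names")
  }
  labels <- c("O", unlist(lapply(entity_types, function(ty) {
    paste0(c("B-", "I-", "E-", "S-"), ty)
  })))
  structure(
    list(labels = labels, types = entity_types,
         index = stats::setNames(seq_along(labels), labels)),
    class = "tag_alphabet"
  )
}

#' @export
print.tag_alphabet <- function(x, ...) {
  cat("BIEOS tag alphabet:", length(x$labels), "labels,",
      length(x$types), "entity types\n")
  cat("  types:", paste(x$types, collapse = ", "), "\n")
  invisible(x)
}

# Split a tag into its positional prefix ("B","I","E","S","O") and type.
split_tag <- function(tags) {
  pre <- ifelse(tags == "O", "O", substr(tags, 1L, 1L))
  ty <- ifelse(tags == "O", NA_character_, substr(tags, 3L, nchar(tags)))
  list(prefix = pre, type = ty)
}

#' Validate a BIEOS tag sequence
#'
#' A sequence is BIEOS-valid when I/E tags only continue a B/I tag of the
#' same type, every B/I is eventually closed by an E of that type, and S/O
#' stand alone.
#'
#' @param tags character vector of tags.
#' @return `TRUE` if valid, otherwise `FALSE` with attribute `"reason"`
#'   naming the first offending position.
#' @export
is_bieos_valid <- function(tags) {
  fail <- function(i, why) {
    structure(FALSE, reason = sprintf("position %d: %s", i, why))
  }
  st <- split_tag(tags)
  open_type <- NA_character_  # type of currently open B.../I... run
  for (i in seq_along(tags)) {
    p <- st$prefix[i]; ty <- st$type[i]
    if (!p %in% c("B", "I", "E", "S", "O")) return(fail(i, "unknown tag prefix"))
    if (p %in% c("B", "I", "E", "S") && (is.na(ty) || !nzchar(ty))) {
      return(fail(i, "missing entity type"))
    }
    if (is.na(open_type)) {
      if (p %in% c("I", "E")) return(fail(i, sprintf("%s- without an open entity", p)))
      if (p == "B") open_type <- ty
    } else {
      if (!p %in% c("I", "E")) {
        return(fail(i, "open entity not closed by E-"))
      }
      if (ty != open_type) return(fail(i, "entity type changes mid-span"))
      if (p == "E") open_type <- NA_character_
    }
  }
  if (!is.na(open_type)) {
    return(fail(length(tags), "sentence ends inside an open entity"))
  }
  TRUE
}

#' Convert an IOB2 tag sequence to BIEOS
#'
#' Rewrites Begin/Inside/Outside tags into the richer
#' Begin/Inside/End/Outside/Single scheme. The entity spans induced by the
#' input and output sequences are identical; only boundary marking changes
#' (a one-token entity becomes `S-`, the last token of a longer entity
#' becomes `E-`).
#'
#' @param tags character vector of IOB2 tags (`O`, `B-type`, `I-type`).
#' @return character vector of BIEOS tags, same length.
#' @examples
#' iob2_to_bieos(c("B-protein", "I-protein", "O", "B-DNA"))
#' @export
iob2_to_bieos <- function(tags) {
  n <- length(tags)
  if (n == 0L) return(character(0))
  st <- split_tag(tags)
  for (i in seq_len(n)) {
    p <- st$prefix[i]
    if (!p %in% c("B", "I", "O")) {
      stop_config("invalid IOB2 tag '%s' at position %d", tags[i], i)
    }
    if (p == "I") {
      ok <- i > 1L && st$prefix[i - 1L] %in% c("B", "I") &&
        identical(st$type[i - 1L], st$type[i])
      if (!ok) {
        stop_config("IOB2-invalid input: I- with no preceding B-/I- of the same type at position %d", i)
      }
    }
  }
  out <- tags
  last_of_run <- function(i) {
    i == n || !(st$prefix[i + 1L] == "I" && identical(st$type[i + 1L], st$type[i]))
  }
  for (i in seq_len(n)) {
    p <- st$prefix[i]
    if (p == "O") next
    last <- last_of_run(i)
    out[i] <- if (p == "B" && last) paste0("S-", st$type[i])
      else if (p == "B") paste0("B-", st$type[i])
      else if (last) paste0("E-", st$type[i])
      else paste0("I-", st$type[i])
  }
  out
}

#' Extract entity spans from a BIEOS tag sequence
#'
#' Returns the entity mentions encoded by a tag sequence as half-open,
#' 0-based token intervals `[start, end)`. The function is total: invalid
#' predicted sequences (which an unconstrained decoder can emit) are
#' repaired deterministically rather than rejected -- a stray `I-`/`E-`
#' opens a new span as if it were `B-`, and a `B-`/`I-` followed by an
#' incompatible tag closes its span at that boundary.
#'
#' @param tags character vector of BIEOS tags.
#' @return a data.frame with columns `start` (0-based, inclusive),
#'   `end` (exclusive) and `type`; zero rows when no entity is present.
#' @examples
#' bieos_to_spans(c("B-protein", "E-protein", "O", "S-DNA"))
#' @export
bieos_to_spans <- function(tags) {
  n <- length(tags)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  st <- split_tag(tags)
  open_start <- NA_integer_; open_type <- NA_character_
  close_open <- function(end_pos) {
    starts[[length(starts) + 1L]] <<- open_start
    ends[[length(ends) + 1L]] <<- end_pos
    types[[length(types) + 1L]] <<- open_type
    open_start <<- NA_integer_; open_type <<- NA_character_
  }
  for (i in seq_len(n)) {
    p <- st$prefix[i]; ty <- st$type[i]
    if (!is.na(open_start) && (p %in% c("O", "B", "S") ||
        (p %in% c("I", "E") && ty != open_type))) {
      close_open(i - 1L)  # incompatible tag closes the open span here
    }
    if (p == "S") {
      starts[[length(starts) + 1L]] <- i - 1L
      ends[[length(ends) + 1L]] <- i
      types[[length(types) + 1L]] <- ty
    } else if (p == "B" || (p %in% c("I", "E") && is.na(open_start))) {
      # B opens; stray I/E open a new span as if B
      open_start <- i - 1L; open_type <- ty
      if (p == "E") close_open(i)
    } else if (p == "E") {
      close_open(i)
    }
    # plain I inside a compatible open span: continue
  }
  if (!is.na(open_start)) close_open(n)  # unterminated run closes at sentence end
  data.frame(start = starts, end = ends, type = types,
             stringsAsFactors = FALSE)
}

#' Extract spans from an IOB2 tag sequence
#'
#' Brute-force span extractor working directly on IOB2 runs; used as an
#' independent cross-check that scheme conversion preserves span sets.
#'
#' @param tags character vector of IOB2 tags.
#' @return data.frame as [bieos_to_spans()].
#' @export
iob2_to_spans <- function(tags) {
  n <- length(tags)
  st <- split_tag(tags)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  i <- 1L
  while (i <= n) {
    if (st$prefix[i] == "B") {
      j <- i
      while (j < n && st$prefix[j + 1L] == "I" &&
             identical(st$type[j + 1L], st$type[i])) j <- j + 1L
      starts <- c(starts, i - 1L); ends <- c(ends, j); types <- c(types, st$type[i])
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, end = ends, type = types, stringsAsFactors = FALSE)
}

#' Render tags for a set of entity spans
#'
#' Inverse of [bieos_to_spans()] for non-overlapping spans: produces the
#' BIEOS tag sequence encoding the given entities.
#'
#' @param spans data.frame with `start`, `end`, `type` (half-open, 0-based).
#' @param length sentence length in tokens.
#' @return character vector of BIEOS tags.
#' @export
spans_to_bieos <- function(spans, length) {
  tags <- rep("O", length)
  if (nrow(spans)) {
    for (r in seq_len(nrow(spans))) {
      s <- spans$start[r]; e <- spans$end[r]; ty <- spans$type[r]
      if (s < 0 || e > length || s >= e) {
        stop_config("invalid span [%d,%d) for sentence of length %d", s, e, length)
      }
      if (e - s == 1L) {
        tags[s + 1L] <- paste0("S-", ty)
      } else {
        tags[s + 1L] <- paste0("B-", ty)
        if (e - s > 2L) tags[(s + 2L):(e - 1L)] <- paste0("I-", ty)
        tags[e] <- paste0("E-", ty)
      }
    }
  }
  tags
}
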