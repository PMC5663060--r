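# Token normalization applied before word-embedding lookup.

#' Normalize a token for word-embedding lookup
#'
#' Lowercases the token and replaces numeric content with the literal
#' `NUM`. Two digit conventions are supported:
#' \describe{
#'   \item{`"digit_run"` (default)}{every maximal run of digits inside the
#'     token becomes `NUM`, so `"IL-2"` -> `"il-NUM"` and `"1234"` ->
#'     `"NUM"`. This maximizes embedding-vocabulary hits for alphanumeric
#'     biomedical tokens.}
#'   \item{`"whole_token"`}{only tokens consisting entirely of digits
#'     become `NUM`; other tokens are merely lowercased.}
#' }
#' The function is deterministic and idempotent: the literal `NUM` is
#' reserved and passes through unchanged, so re-normalizing an already
#' normalized token is the identity.
#'
#' Character-level indexing intentionally uses the raw surface form, not
#' this normalization: the character model exists to capture the
#' orthography (case, digits) that word normalization destroys.
#'
#' @param surface character vector of raw token strings.
#' @param digits one of `"digit_run"` or `"whole_token"`.
#' @return character vector of normalized tokens.
#' @examples
#' normalize_token(c("Characterization", "1234", "IL-2"))
#' normalize_token("IL-2", digits = "whole_token")
#' @export
normalize_token <- function(surface, digits = c("digit_run", "whole_token")) {
  digits <- match.arg(digits)
  ph <- "\x01"  # placeholder protecting the reserved NUM literal
  out <- gsub("NUM", ph, surface, fixed = TRUE)
  out <- tolower(out)
  if (digits == "digit_run") {
    out <- gsub("[0-9]+", ph, out)
  } else {
    out[grepl("^[0-9]+$", out)] <- ph
  }
  gsub(ph, "NUM", out, fixed = TRUE)
}
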