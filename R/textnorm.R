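#' Normalize a raw scientific-name string
#'
#' Applies, in order: (a) removal of special characters (question marks,
#' exclamation marks, hashtags, quotes and double quotes; underscores are
#' replaced by a blank so `"Genus_species"` stays two tokens); (b) removal
#' of digits (the reference checklist carries no years); (c) transliteration
#' of letters with diacritics to their ASCII equivalents; (d) insertion of a
#' blank after every dot not already followed by one; (e) removal of the
#' uncertainty tokens `"cf."` and `"aff."` (standalone, with or without the
#' trailing dot, case-insensitive; `"cfr."` too when `cfr_alias` is on);
#' (f) collapsing of blank runs and trimming of leading/trailing blanks.
#'
#' Any residual character outside the legal name alphabet (ASCII letters,
#' blank, dot, parentheses, ampersand, hyphen, comma) is dropped after step
#' (c), so the output alphabet is guaranteed. The function is total and
#' idempotent; empty input yields empty output.
#'
#' @param raw Character vector of raw name strings.
#' @param cfr_alias Also treat `"cfr."` as an uncertainty token (default
#'   `FALSE`).
#' @return Character vector of normalized strings.
#' @examples
#' normalize_string("Carex cf. flava")   # "Carex flava"
#' normalize_string("R.canina  2")       # "R. canina"
#' @export
normalize_string <- function(raw, cfr_alias = FALSE) {
  stopifnot(is.character(raw))
  x <- raw
  # (a) special characters; underscore becomes a blank
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("[?!#'\"“”‘’«»‹›`´]", "", x)
  # (b) digits
  x <- gsub("[0-9]", "", x)
  # (c) diacritics to ASCII (handles o-slash and sharp-s as well)
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  # residual characters outside the legal name alphabet
  x <- gsub("[^A-Za-z .()&,-]", "", x)
  # (d) blank after every dot
  x <- gsub("\\.(?=[^ ])", ". ", x, perl = TRUE)
  # (e) uncertainty tokens, standalone, optional trailing dot
  unc <- if (isTRUE(cfr_alias)) "(cf|aff|cfr)" else "(cf|aff)"
  x <- gsub(paste0("(?i)(^|(?<= ))", unc, "\\.?((?= )|$)"), "", x, perl = TRUE)
  # (f) blank runs, ends
  x <- gsub("[[:blank:]]+", " ", x)
  trimws(x)
}
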