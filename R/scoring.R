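# Component-wise scoring of a candidate match.
#
# Each name component (genus, species epithet, infraspecific epithets) gets
# ComponentScore = 1 - ED / maxED, where ED is the MDLD distance and maxED
# the length of the longer of the two strings. The taxon score is the mean
# of the component scores; authorities contribute a separate n-gram score;
# ReturnedScore = (TaxonScore * 0.9 + AuthorScore * 0.1) * 100.

#' Component score from an edit distance
#'
#' `1 - ed / max(len_input, len_reference)`: the fraction of the longer
#' string left unedited.
#'
#' @param ed Non-negative integer edit distance (MDLD).
#' @param len_input,len_reference Lengths of the two compared strings; at
#'   least one must be positive.
#' @return Score in `[0, 1]`.
#' @examples
#' component_score(2, 10, 11) # 0.8182 ("milefolius" vs "millefolium")
#' @export
component_score <- function(ed, len_input, len_reference) {
  maxed <- max(len_input, len_reference)
  if (maxed < 1) stop("no component to score: both lengths are 0", call. = FALSE)
  stopifnot(ed >= 0, ed <= maxed)
  1 - ed / maxed
}

#' Wrong-rank penalty on an infraspecific component score
#'
#' The component score of an infraspecific epithet is decreased by 0.3 when
#' the rank indicator is not the correct one (e.g. `var.` typed where the
#' reference has `subsp.`), floored at 0. An unknown input rank is not
#' penalized: with no recognizable indicator there is nothing to be wrong
#' about.
#'
#' @param score Component score in `[0, 1]`.
#' @param input_rank,reference_rank Rank strings (`"subspecies"`,
#'   `"variety"`, `"form"`, `"cultivar"`, or `"unknown"`/`NA`).
#' @return Penalized score in `[0, 1]`.
#' @examples
#' apply_rank_penalty(1.0, "variety", "subspecies") # 0.7
#' @export
apply_rank_penalty <- function(score, input_rank, reference_rank) {
  stopifnot(score >= 0, score <= 1)
  unknown <- function(r) is.na(r) || !nzchar(r) || identical(r, "unknown")
  if (unknown(input_rank) || unknown(reference_rank)) return(score)
  if (identical(input_rank, reference_rank)) return(score)
  max(score - 0.3, 0)
}

#' Taxon score: mean of the component scores
#'
#' @param components Numeric vector of component scores (genus, species,
#'   each infraspecific epithet present).
#' @return Mean score in `[0, 1]`.
#' @examples
#' taxon_score(c(1, 1, 0.7)) # 0.9
#' @export
taxon_score <- function(components) {
  if (length(components) == 0L) {
    stop("taxon_score() needs at least one component", call. = FALSE)
  }
  stopifnot(all(components >= 0), all(components <= 1))
  mean(components)
}

#' Returned score of a candidate
#'
#' `(taxon * 0.9 + author * 0.1) * 100`, on the 0-100 scale shown to users.
#' The taxon name carries 90% of the weight, the authority 10%.
#'
#' @param taxon,author Scores in `[0, 1]`.
#' @return Score in `[0, 100]`.
#' @examples
#' returned_score(1, 1) # 100
#' returned_score(1, 0) # 90
#' @export
returned_score <- function(taxon, author) {
  stopifnot(taxon >= 0, taxon <= 1, author >= 0, author <= 1)
  (taxon * 0.9 + author * 0.1) * 100
}

#' Authority similarity with missing-side handling
#'
#' [ngram_similarity()] between two authority strings, with the convention
#' that two absent authorities are a perfect agreement (a bare binomial
#' matched against a bare binomial stays at 100) while an authority present
#' on exactly one side scores 0.
#'
#' @param a,b Authority strings (possibly empty).
#' @return Score in `[0, 1]`.
#' @export
author_score <- function(a, b) {
  ea <- !nzchar(trimws(a))
  eb <- !nzchar(trimws(b))
  if (ea && eb) return(1)
  if (ea || eb) return(0)
  ngram_similarity(a, b)
}
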