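#' Matching options
#'
#' Collects every user-tunable setting of the list matcher and the parser.
#'
#' @param separator Field separator for CSV name lists: one of `"comma"`,
#'   `"semicolon"`, `"colon"`, `"tab"` (or the literal character).
#' @param name_column Header name (or numeric index) of the column hosting
#'   the taxon names in CSV mode.
#' @param rank_aliases Named list of extra rank indicators per rank, e.g.
#'   `list(subspecies = "s", cultivar = "c")`. Consulted before the built-in
#'   alias tables; this is also how the single letters `"s."` and `"c."`
#'   are enabled as rank indicators (they are off by default because they
#'   are rarely used that way).
#' @param phonetic_enabled Use the phonetic test alongside the orthographic
#'   one (default `TRUE`). Disabling it never adds candidates.
#' @param threshold Integer 1-100; candidates scoring below it are not
#'   returned (default 70). At 100 only exact matches survive.
#' @param force_case_insensitive Parse without using capitalization as a
#'   signal even when the input is mixed-case (default `FALSE`).
#' @param max_names Cap on the number of distinct names accepted in one
#'   list (default 5000).
#' @param ambiguity_margin A match is unambiguous when the best candidate
#'   leads the runner-up by at least this many returned-score points
#'   (default 5).
#' @param mdld_block_limit Block length cap for [mdld()] (default 2).
#' @param query_edit_cap Maximum total edits allowed by
#'   [nearest_query_match()] (default 2).
#' @param genus_ed_cap Maximum MDLD distance for a genus to survive the
#'   first matching stage (default 2).
#' @param epithet_ed_cap Maximum MDLD distance for a species or
#'   infraspecific epithet to pass the orthographic test (default 3).
#' @param cfr_alias Treat `"cfr."` as an uncertainty token in
#'   [normalize_string()] (default `FALSE`).
#' @param seed Optional integer seed recorded with synthetic/test runs.
#' @return An object of class `match_options` (a named list).
#' @examples
#' opts <- match_options(threshold = 80, phonetic_enabled = FALSE)
#' opts$threshold
#' @export
match_options <- function(separator = "comma",
                          name_column = NULL,
                          rank_aliases = list(),
                          phonetic_enabled = TRUE,
                          threshold = 70L,
                          force_case_insensitive = FALSE,
                          max_names = 5000L,
                          ambiguity_margin = 5,
                          mdld_block_limit = 2L,
                          query_edit_cap = 2L,
                          genus_ed_cap = 2L,
                          epithet_ed_cap = 3L,
                          cfr_alias = FALSE,
                          seed = NULL) {
  sep_map <- c(comma = ",", semicolon = ";", colon = ":", tab = "\t")
  if (separator %in% names(sep_map)) {
    sep_char <- unname(sep_map[[separator]])
  } else if (separator %in% sep_map) {
    sep_char <- separator
    separator <- names(sep_map)[match(separator, sep_map)]
  } else {
    stop("separator must be one of ", paste(names(sep_map), collapse = ", "),
         call. = FALSE)
  }
  threshold <- as.integer(threshold)
  stopifnot(threshold >= 1L, threshold <= 100L)
  max_names <- as.integer(max_names)
  stopifnot(max_names >= 1L)
  stopifnot(is.list(rank_aliases))
  if (length(rank_aliases) > 0L) {
    bad <- setdiff(names(rank_aliases),
                   c("subspecies", "variety", "form", "cultivar"))
    if (length(bad) > 0L || is.null(names(rank_aliases))) {
      stop("rank_aliases must be named with ranks among ",
           "subspecies, variety, form, cultivar", call. = FALSE)
    }
  }
  structure(list(
    separator = separator,
    sep_char = sep_char,
    name_column = name_column,
    rank_aliases = rank_aliases,
    phonetic_enabled = isTRUE(phonetic_enabled),
    threshold = threshold,
    force_case_insensitive = isTRUE(force_case_insensitive),
    max_names = max_names,
    ambiguity_margin = as.numeric(ambiguity_margin),
    mdld_block_limit = as.integer(mdld_block_limit),
    query_edit_cap = as.integer(query_edit_cap),
    genus_ed_cap = as.integer(genus_ed_cap),
    epithet_ed_cap = as.integer(epithet_ed_cap),
    cfr_alias = isTRUE(cfr_alias),
    seed = seed
  ), class = "match_options")
}

as_match_options <- function(options) {
  if (is.null(options)) return(match_options())
  if (inherits(options, "match_options")) return(options)
  stop("options must be created with match_options()", call. = FALSE)
}
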