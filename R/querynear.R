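# Constrained near match for interactive query strings.
#
# A free-text (possibly partial) query is corrected to the closest
# substring occurring in the reference names, under two constraints:
# the corrected string may be longer or shorter than the query by at most
# one character, and blanks are sacrosanct — never inserted, never
# replaced, and every query blank maps to a blank.

#' Correct a query string to the nearest substring of the reference names
#'
#' If the query already occurs (case-insensitively) inside a reference full
#' name it is returned uncorrected. Otherwise every window of length
#' `nchar(query) - 1` to `nchar(query) + 1` of every reference name is
#' scored with a blank-locked edit distance (aligning a blank to a
#' non-blank is forbidden, as is inserting or deleting a blank) and the
#' cheapest correction within `options$query_edit_cap` edits wins. Ties are
#' broken by the number of reference entries containing the corrected
#' string, then lexicographically.
#'
#' @param query The query string (non-empty after blank collapsing).
#' @param thesaurus A `thesaurus` (see [build_thesaurus()]).
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @return An object of class `query_correction`: list with `query`,
#'   `corrected` (empty when nothing qualifies), `edit_cost`,
#'   `matched_entries` (entry ids whose full name contains the corrected
#'   string) and `was_corrected`.
#' @examples
#' rows <- data.frame(full_name = c("Calendula officinalis L.",
#'                                  "Galega officinalis L."),
#'                    status = "accepted", accepted_ref = "")
#' th <- build_thesaurus(rows)
#' nearest_query_match("officialis", th)$corrected # "officinalis"
#' @export
nearest_query_match <- function(query, thesaurus, options = NULL) {
  stopifnot(is.character(query), length(query) == 1L,
            inherits(thesaurus, "thesaurus"))
  options <- as_match_options(options)
  q <- trimws(gsub("[[:blank:]]+", " ", query))
  if (!nzchar(q)) stop("query is empty after normalization", call. = FALSE)
  names_all <- thesaurus$entries$full_name
  ids_all <- thesaurus$entries$entry_id
  ql <- tolower(q)

  contains <- function(sub) {
    ids_all[grepl(sub, tolower(names_all), fixed = TRUE)]
  }

  hit <- contains(ql)
  if (length(hit) > 0L) {
    return(structure(list(query = q, corrected = q, edit_cost = 0L,
                          matched_entries = sort(hit), was_corrected = FALSE),
                     class = "query_correction"))
  }
  nq <- nchar(q)
  acc <- vector("list", length(names_all))
  for (idx in seq_along(names_all)) {
    nm <- names_all[idx]
    nn <- nchar(nm)
    w <- character(0)
    for (L in (nq - 1L):(nq + 1L)) {
      if (L < 1L || L > nn) next
      starts <- seq_len(nn - L + 1L)
      w <- c(w, substring(nm, starts, starts + L - 1L))
    }
    acc[[idx]] <- w
  }
  wins <- unlist(acc, use.names = FALSE)
  if (length(wins) == 0L) {
    return(.no_correction(q))
  }
  wins <- wins[!duplicated(tolower(wins))]
  # plain Levenshtein lower-bounds the blank-locked distance
  lev <- as.integer(utils::adist(ql, tolower(wins)))
  wins <- wins[lev <= options$query_edit_cap]
  if (length(wins) == 0L) return(.no_correction(q))
  cost <- vapply(wins, function(w) .blank_locked_ed(ql, tolower(w)), numeric(1L),
                 USE.NAMES = FALSE)
  ok <- is.finite(cost) & cost <= options$query_edit_cap
  if (!any(ok)) return(.no_correction(q))
  wins <- wins[ok]
  cost <- as.integer(cost[ok])
  best <- min(cost)
  wins <- wins[cost == best]
  matches <- lapply(tolower(wins), contains)
  nmatch <- lengths(matches)
  ord <- order(-nmatch, tolower(wins))
  pick <- ord[1L]
  structure(list(query = q, corrected = wins[pick], edit_cost = best,
                 matched_entries = sort(matches[[pick]]), was_corrected = TRUE),
            class = "query_correction")
}

.no_correction <- function(q) {
  structure(list(query = q, corrected = "", edit_cost = NA_integer_,
                 matched_entries = integer(0), was_corrected = TRUE),
            class = "query_correction")
}

# Edit distance in which blanks only ever align to blanks: substituting a
# blank for a non-blank (either direction), inserting a blank, or deleting
# a blank all cost Inf.
.blank_locked_ed <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(av)
  n <- length(bv)
  d <- matrix(Inf, m + 1L, n + 1L)
  d[1L, 1L] <- 0
  for (i in seq_len(m)) {
    d[i + 1L, 1L] <- if (av[i] == " ") Inf else d[i, 1L] + 1
  }
  for (j in seq_len(n)) {
    d[1L, j + 1L] <- if (bv[j] == " ") Inf else d[1L, j] + 1
  }
  for (i in seq_len(m)) {
    ab <- av[i] == " "
    for (j in seq_len(n)) {
      bb <- bv[j] == " "
      sub_cost <- if (av[i] == bv[j]) 0 else if (ab || bb) Inf else 1
      del_cost <- if (ab) Inf else 1
      ins_cost <- if (bb) Inf else 1
      d[i + 1L, j + 1L] <- min(d[i, j] + sub_cost,
                               d[i, j + 1L] + del_cost,
                               d[i + 1L, j] + ins_cost)
    }
  }
  d[m + 1L, n + 1L]
}

#' @export
print.query_correction <- function(x, ...) {
  if (!x$was_corrected) {
    cat("<query_correction> ", sQuote(x$query), ": exact substring (",
        length(x$matched_entries), " entries)\n", sep = "")
  } else if (nzchar(x$corrected)) {
    cat("<query_correction> ", sQuote(x$query), " -> ", sQuote(x$corrected),
        " (", x$edit_cost, " edit(s), ", length(x$matched_entries),
        " entries)\n", sep = "")
  } else {
    cat("<query_correction> ", sQuote(x$query), ": no correction found\n",
        sep = "")
  }
  invisible(x)
}
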