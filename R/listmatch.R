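# Batch list matching: read a names list, dedupe, run the four-stage
# matcher on every name, tally the report, write the four-column CSV.

#' Read a list of names from a text or CSV file
#'
#' Text mode (the default) expects one name per line. CSV mode (activated
#' by `options$name_column`) reads the designated column with the
#' separator from `options$separator`. Names are normalized and
#' deduplicated (first occurrence wins); the raw count is kept for the
#' report. With `options$force_case_insensitive` the deduplication is
#' case-insensitive as well.
#'
#' @param path Path to the input file.
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @return List with `names` (distinct raw names, first-occurrence order)
#'   and `total` (raw row count). Errors when the file is missing, the
#'   column is absent, or the distinct names exceed `options$max_names`.
#' @export
read_name_list <- function(path, options = NULL) {
  options <- as_match_options(options)
  if (!file.exists(path)) {
    stop("name list not found: ", path, call. = FALSE)
  }
  if (is.null(options$name_column)) {
    raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
    raw <- trimws(raw)
    raw <- raw[nzchar(raw)]
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = options$sep_char,
                             quote = "\"", comment.char = "",
                             stringsAsFactors = FALSE, fill = TRUE,
                             colClasses = "character", encoding = "UTF-8")
    col <- options$name_column
    if (is.numeric(col)) {
      if (col < 1L || col > ncol(tab)) {
        stop("name column index ", col, " out of range", call. = FALSE)
      }
    } else if (!col %in% names(tab)) {
      stop("name column ", sQuote(col), " not found in ", path, call. = FALSE)
    }
    raw <- trimws(tab[[col]])
    raw <- raw[nzchar(raw)]
  }
  total <- length(raw)
  key <- normalize_string(raw, cfr_alias = options$cfr_alias)
  if (options$force_case_insensitive) key <- tolower(key)
  distinct <- raw[!duplicated(key)]
  if (length(distinct) > options$max_names) {
    stop("the list has ", length(distinct), " distinct names; the limit is ",
         options$max_names, call. = FALSE)
  }
  list(names = distinct, total = total)
}

#' Match a list of distinct names against the thesaurus
#'
#' Runs [match_name()] on every name (normalization, exact pre-processing,
#' parsing with the flagged-token re-check, fuzzy matching,
#' classification), preserving input order. Individual parse failures
#' become `none` results with a note; they never abort the batch.
#'
#' @param names Character vector of distinct names (see
#'   [read_name_list()]).
#' @param thesaurus A `thesaurus`.
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @param total Raw (pre-deduplication) name count for the report;
#'   defaults to `length(names)`.
#' @return List with `results` (list of `match_result`) and `report` (a
#'   `list_match_report`: counts of exact, unambiguous, ambiguous and
#'   unmatched names plus the elapsed time).
#' @export
run_list_match <- function(names, thesaurus, options = NULL,
                           total = length(names)) {
  options <- as_match_options(options)
  stopifnot(is.character(names))
  if (length(names) == 0L) {
    stop("the name list is empty", call. = FALSE)
  }
  t0 <- proc.time()[["elapsed"]]
  results <- lapply(names, function(nm) match_name(nm, thesaurus, options))
  elapsed <- proc.time()[["elapsed"]] - t0
  statuses <- vapply(results, `[[`, "", "status")
  report <- structure(list(
    total_names = as.integer(total),
    distinct_names = length(names),
    n_exact = sum(statuses == "exact"),
    n_unambiguous = sum(statuses == "unambiguous"),
    n_ambiguous = sum(statuses == "ambiguous"),
    n_none = sum(statuses == "none"),
    elapsed = elapsed
  ), class = "list_match_report")
  list(results = results, report = report)
}

#' Write match results as the four-column CSV
#'
#' Columns: `original_name`, `accepted_name`, `synonym`, `score`. The
#' `synonym` column is filled only when the chosen match is a synonym
#' entry, in which case `accepted_name` holds its accepted target.
#' Ambiguous rows carry the top candidate with the score marked by a
#' trailing asterisk; unmatched rows have empty name cells and score 0.
#'
#' @param results List of `match_result` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  if (length(results) == 0L) {
    stop("no results to write", call. = FALSE)
  }
  fmt_score <- function(s) {
    x <- round(s, 2)
    if (x == as.integer(x)) sprintf("%d", as.integer(x)) else sprintf("%.2f", x)
  }
  rows <- lapply(results, function(r) {
    score <- if (r$status == "none") "0" else fmt_score(r$score)
    if (r$status == "ambiguous") score <- paste0(score, "*")
    data.frame(original_name = r$raw_input,
               accepted_name = r$accepted_name,
               synonym = r$synonym_name,
               score = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.list_match_report <- function(x, ...) {
  cat("<list_match_report>\n",
      "  names in the original list: ", x$total_names, "\n",
      "  distinct names:             ", x$distinct_names, "\n",
      "  exact matches:              ", x$n_exact, "\n",
      "  unambiguous matches:        ", x$n_unambiguous, "\n",
      "  ambiguous matches:          ", x$n_ambiguous, "\n",
      "  no match:                   ", x$n_none, "\n",
      "  elapsed:                    ", sprintf("%.2f s", x$elapsed), "\n",
      sep = "")
  invisible(x)
}
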