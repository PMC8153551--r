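# The reference checklist: loading, parsing, indexing, persistence.
#
# Entries are kept in a flat data frame (one column per parsed component)
# so the whole thesaurus is vectorizable during matching and serializes to
# a single delimited file.

.ENTRY_COLS <- c(
  "entry_id", "full_name", "status", "accepted_id", "normalized",
  "genus", "genus_phon", "species", "species_phon", "species_auth",
  "infra1_rank", "infra1_token", "infra1_epithet", "infra1_phon", "infra1_auth",
  "infra2_rank", "infra2_token", "infra2_epithet", "infra2_phon", "infra2_auth",
  "parse_flag"
)

#' Load a reference checklist file
#'
#' Reads a delimited checklist with one scientific name per row, a status
#' column (`accepted` or `synonym`, any capitalization) and, for synonyms,
#' the verbatim full name of the accepted entry they point to.
#'
#' @param path Path to the checklist file.
#' @param dialect List with `sep` (field separator, default `","`) and the
#'   column names `name`, `status`, `accepted` (defaults `"name"`,
#'   `"status"`, `"accepted_name"`).
#' @return A data frame with columns `full_name`, `status`, `accepted_ref`
#'   in file order.
#' @export
load_checklist <- function(path, dialect = list()) {
  if (!file.exists(path)) {
    stop("checklist file not found: ", path, call. = FALSE)
  }
  dialect <- utils::modifyList(
    list(sep = ",", name = "name", status = "status", accepted = "accepted_name"),
    dialect)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character", encoding = "UTF-8")
  for (col in c(dialect$name, dialect$status, dialect$accepted)) {
    if (!col %in% names(raw)) {
      stop("checklist is missing the mapped column ", sQuote(col), call. = FALSE)
    }
  }
  rows <- data.frame(
    full_name = trimws(raw[[dialect$name]]),
    status = tolower(trimws(raw[[dialect$status]])),
    accepted_ref = trimws(raw[[dialect$accepted]]),
    stringsAsFactors = FALSE
  )
  if (nrow(rows) == 0L) return(rows)
  bad_status <- which(!rows$status %in% c("accepted", "synonym"))
  if (length(bad_status) > 0L) {
    stop("row ", bad_status[1L], ": unknown status ",
         sQuote(rows$status[bad_status[1L]]),
         " (expected accepted or synonym)", call. = FALSE)
  }
  empty <- which(!nzchar(rows$full_name))
  if (length(empty) > 0L) {
    stop("row ", empty[1L], ": empty name", call. = FALSE)
  }
  accepted_names <- rows$full_name[rows$status == "accepted"]
  syn <- which(rows$status == "synonym")
  missing_ref <- syn[!rows$accepted_ref[syn] %in% accepted_names]
  if (length(missing_ref) > 0L) {
    stop("row ", missing_ref[1L], ": synonym ",
         sQuote(rows$full_name[missing_ref[1L]]),
         " points to an accepted name not present in the checklist: ",
         sQuote(rows$accepted_ref[missing_ref[1L]]), call. = FALSE)
  }
  rows
}

#' Build a parsed, indexed thesaurus from checklist rows
#'
#' Parses every reference name into its components (with phonetic keys for
#' genus and each epithet) and builds two indexes: genus phonetic key ->
#' entry ids, and normalized full name -> entry ids. Rows that cannot be
#' parsed are quarantined with a reason rather than dropped silently or
#' allowed to abort the build. Duplicate full names keep the first
#' occurrence with a warning.
#'
#' @param rows Data frame from [load_checklist()] (columns `full_name`,
#'   `status`, `accepted_ref`).
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @return An object of class `thesaurus`: list with `entries` (flat data
#'   frame, one column per parsed component), `quarantine` (data frame of
#'   rejected rows), `genus_index` and `name_index` (environments).
#' @examples
#' rows <- data.frame(
#'   full_name = c("Achillea millefolium L.", "Achillea sudetica Opiz"),
#'   status = c("accepted", "synonym"),
#'   accepted_ref = c("", "Achillea millefolium L."))
#' th <- build_thesaurus(rows)
#' nrow(th$entries)
#' @export
build_thesaurus <- function(rows, options = NULL) {
  options <- as_match_options(options)
  stopifnot(is.data.frame(rows),
            all(c("full_name", "status", "accepted_ref") %in% names(rows)))
  n <- nrow(rows)
  quarantine <- data.frame(row = integer(0), full_name = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  if (n > 0L) {
    dup <- duplicated(rows$full_name)
    if (any(dup)) {
      warning(sum(dup), " duplicate full name(s) in the checklist; ",
              "keeping first occurrence (e.g. ",
              sQuote(rows$full_name[which(dup)[1L]]), ")", call. = FALSE)
      rows <- rows[!dup, , drop = FALSE]
      n <- nrow(rows)
    }
  }

  recs <- vector("list", n)
  for (i in seq_len(n)) {
    full <- rows$full_name[i]
    norm <- normalize_string(full, cfr_alias = options$cfr_alias)
    parsed <- tryCatch(parse_name(norm, options), error = function(e) e)
    if (inherits(parsed, "error")) {
      quarantine <- rbind(quarantine, data.frame(
        row = i, full_name = full, reason = conditionMessage(parsed),
        stringsAsFactors = FALSE))
      next
    }
    inf <- function(k, field) {
      if (length(parsed$infra) >= k) parsed$infra[[k]][[field]] else ""
    }
    recs[[i]] <- data.frame(
      entry_id = NA_integer_, full_name = full, status = rows$status[i],
      accepted_id = NA_integer_, normalized = norm,
      genus = parsed$genus, genus_phon = parsed$genus_phonetic,
      species = parsed$species_epithet, species_phon = parsed$species_phonetic,
      species_auth = parsed$species_authority,
      infra1_rank = inf(1L, "rank"), infra1_token = inf(1L, "rank_token"),
      infra1_epithet = inf(1L, "epithet"), infra1_phon = inf(1L, "epithet_phonetic"),
      infra1_auth = inf(1L, "authority"),
      infra2_rank = inf(2L, "rank"), infra2_token = inf(2L, "rank_token"),
      infra2_epithet = inf(2L, "epithet"), infra2_phon = inf(2L, "epithet_phonetic"),
      infra2_auth = inf(2L, "authority"),
      parse_flag = parsed$parse_flag,
      stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
  if (is.null(entries)) {
    entries <- as.data.frame(
      sapply(.ENTRY_COLS, function(x) character(0), simplify = FALSE),
      stringsAsFactors = FALSE)
    entries$entry_id <- integer(0)
    entries$accepted_id <- integer(0)
  } else {
    entries$entry_id <- seq_len(nrow(entries))
    # resolve synonym pointers (kept rows only; targets were validated at load)
    tgt <- match(rows$accepted_ref[match(entries$full_name, rows$full_name)],
                 entries$full_name)
    is_syn <- entries$status == "synonym"
    tgt_status <- rep(NA_character_, length(tgt))
    tgt_status[!is.na(tgt)] <- entries$status[tgt[!is.na(tgt)]]
    unresolved <- is_syn & (is.na(tgt) | tgt_status != "accepted")
    if (any(unresolved)) {
      quarantine <- rbind(quarantine, data.frame(
        row = which(unresolved), full_name = entries$full_name[unresolved],
        reason = "synonym target unavailable (quarantined or not accepted)",
        stringsAsFactors = FALSE))
      entries <- entries[!unresolved, , drop = FALSE]
      entries$entry_id <- seq_len(nrow(entries))
      tgt <- match(rows$accepted_ref[match(entries$full_name, rows$full_name)],
                   entries$full_name)
      is_syn <- entries$status == "synonym"
    }
    entries$accepted_id <- ifelse(is_syn, tgt, entries$entry_id)
  }
  rownames(entries) <- NULL

  th <- structure(list(
    entries = entries,
    quarantine = quarantine,
    genus_index = .build_index(entries$genus_phon, entries$entry_id),
    name_index = .build_index(entries$normalized, entries$entry_id)
  ), class = "thesaurus")
  th
}

.build_index <- function(keys, ids) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (length(keys) > 0L) {
    sp <- split(ids, keys)
    for (k in names(sp)) assign(k, sp[[k]], envir = env)
  }
  env
}

.index_get <- function(env, key) {
  if (exists(key, envir = env, inherits = FALSE)) {
    get(key, envir = env, inherits = FALSE)
  } else {
    integer(0)
  }
}

#' Persist a thesaurus to a delimited file
#'
#' Writes the parsed entries (one column per component) as a tab-separated
#' UTF-8 file, so builds are cacheable and diffable. [read_thesaurus()]
#' restores the full object, indexes included.
#'
#' @param thesaurus A `thesaurus` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(thesaurus, path) {
  stopifnot(inherits(thesaurus, "thesaurus"))
  utils::write.table(thesaurus$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Restore a thesaurus written by [write_thesaurus()]
#'
#' @param path Path to the persisted thesaurus file.
#' @return A `thesaurus` object.
#' @export
read_thesaurus <- function(path) {
  if (!file.exists(path)) {
    stop("thesaurus file not found: ", path, call. = FALSE)
  }
  entries <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                               comment.char = "", stringsAsFactors = FALSE,
                               colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(.ENTRY_COLS, names(entries))
  if (length(missing_cols) > 0L) {
    stop("not a thesaurus file (missing columns: ",
         paste(missing_cols, collapse = ", "), ")", call. = FALSE)
  }
  entries[is.na(entries)] <- ""
  entries$entry_id <- as.integer(entries$entry_id)
  entries$accepted_id <- as.integer(entries$accepted_id)
  structure(list(
    entries = entries,
    quarantine = data.frame(row = integer(0), full_name = character(0),
                            reason = character(0), stringsAsFactors = FALSE),
    genus_index = .build_index(entries$genus_phon, entries$entry_id),
    name_index = .build_index(entries$normalized, entries$entry_id)
  ), class = "thesaurus")
}

#' Resolve the accepted entry of any entry
#'
#' @param thesaurus A `thesaurus` object.
#' @param entry_id Entry identifier.
#' @return One-row data frame: the accepted entry the id resolves to (the
#'   entry itself when already accepted).
#' @export
accepted_entry <- function(thesaurus, entry_id) {
  stopifnot(inherits(thesaurus, "thesaurus"))
  e <- thesaurus$entries
  i <- match(entry_id, e$entry_id)
  if (is.na(i)) stop("unknown entry_id: ", entry_id, call. = FALSE)
  j <- match(e$accepted_id[i], e$entry_id)
  e[j, , drop = FALSE]
}

#' @export
print.thesaurus <- function(x, ...) {
  e <- x$entries
  cat("<thesaurus> ", nrow(e), " entries (",
      sum(e$status == "accepted"), " accepted, ",
      sum(e$status == "synonym"), " synonyms)",
      if (nrow(x$quarantine) > 0L) paste0("; ", nrow(x$quarantine), " quarantined"),
      "\n", sep = "")
  invisible(x)
}
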