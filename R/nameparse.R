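# Parsing of normalized name strings into classified components.
#
# Token classes used throughout:
#  - epithet-like: bare alphabetic token (hyphen allowed), no dot/parenthesis.
#  - author token: token containing a dot or parenthesis, an authority
#    connective ("ex", "et", "in", "&"), or (in case-sensitive mode) a
#    capitalized word.

.RANK_ALIASES <- list(
  subspecies = c("subsp", "ssp", "subspecies"),
  variety    = c("var", "varietas"),
  form       = c("f", "fo", "forma"),
  cultivar   = c("cv")
)

# single letters that can be either authority parts or rank indicators
.AMBIGUOUS_RANK <- c(v = "variety", f = "form", s = "subspecies", c = "cultivar")

#' Canonical infraspecific rank of an indicator token
#'
#' Maps an indicator token to the rank whose alias table contains a
#' case-insensitive match at Levenshtein distance <= 1 from the dot-stripped
#' token (so `"subsp."`, `"Subsp."` and the typo `"susp"` all map to
#' subspecies). User-supplied aliases in `options$rank_aliases` are
#' consulted first (exact match). Fuzzy (distance-1) matching only applies
#' when both token and alias are at least 3 characters long; shorter
#' indicators such as `"f"` or `"cv"` must match exactly, otherwise any
#' single letter would collide with them.
#'
#' @param token A single word, optionally dot-terminated.
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @return One of `"subspecies"`, `"variety"`, `"form"`, `"cultivar"`, or
#'   `NA_character_` when no alias qualifies. A token equidistant from the
#'   aliases of two different ranks yields `NA` with a warning: ambiguity is
#'   not guessed.
#' @examples
#' canonical_rank("susp")   # "subspecies"
#' canonical_rank("subsp.") # "subspecies"
#' canonical_rank("grandiflora") # NA
#' @export
canonical_rank <- function(token, options = NULL) {
  stopifnot(is.character(token), length(token) == 1L)
  options <- as_match_options(options)
  tok <- tolower(sub("\\.+$", "", token))
  if (!nzchar(tok)) return(NA_character_)
  # user aliases first, exact
  for (rank in names(options$rank_aliases)) {
    al <- tolower(sub("\\.+$", "", options$rank_aliases[[rank]]))
    if (tok %in% al) return(rank)
  }
  tables <- .RANK_ALIASES
  for (rank in names(options$rank_aliases)) {
    tables[[rank]] <- unique(c(
      tolower(sub("\\.+$", "", options$rank_aliases[[rank]])), tables[[rank]]))
  }
  best_rank <- character(0)
  best_d <- Inf
  for (rank in names(tables)) {
    for (al in tables[[rank]]) {
      d <- if (tok == al) {
        0L
      } else if (nchar(tok) >= 3L && nchar(al) >= 3L) {
        levenshtein(tok, al)
      } else {
        NA_integer_
      }
      if (!is.na(d) && d <= 1L) {
        if (d < best_d) {
          best_d <- d
          best_rank <- rank
        } else if (d == best_d && !(rank %in% best_rank)) {
          best_rank <- c(best_rank, rank)
        }
      }
    }
  }
  if (length(best_rank) == 0L) return(NA_character_)
  if (length(best_rank) > 1L) {
    warning("rank indicator '", token, "' matches several ranks (",
            paste(best_rank, collapse = ", "), ") equally well; ignored",
            call. = FALSE)
    return(NA_character_)
  }
  best_rank
}

.is_epithet_like <- function(tok) {
  grepl("^[A-Za-z][A-Za-z-]*$", tok)
}

.is_author_token <- function(tok, case_insensitive) {
  if (!nzchar(tok)) return(FALSE)
  if (grepl("[.()]", tok)) return(TRUE)
  if (tolower(tok) %in% c("ex", "et", "in", "&")) return(TRUE)
  if (!case_insensitive && grepl("^[A-Z]", tok)) return(TRUE)
  FALSE
}

.phon <- function(x) {
  a <- gsub("[^A-Za-z]", "", x)
  if (!nzchar(a)) "" else phonetic_key(a)
}

# which single letters may act as rank indicators under these options
.ambiguous_letters <- function(options) {
  letters_on <- c("v", "f")
  ra <- lapply(options$rank_aliases, function(x) tolower(sub("\\.+$", "", x)))
  if ("s" %in% ra$subspecies) letters_on <- c(letters_on, "s")
  if ("c" %in% ra$cultivar) letters_on <- c(letters_on, "c")
  letters_on
}

#' Parse a normalized scientific name
#'
#' Splits a [normalize_string()]-ed name into genus, species epithet,
#' species authority and up to two infraspecific parts, each with rank
#' indicator, epithet and authority. The first token is the genus; the next
#' bare alphabetic token is the species epithet; tokens up to the first
#' recognized rank indicator belong to the species authority; each rank
#' indicator opens an infraspecific part whose following bare token is the
#' epithet and whose trailing tokens are its authority.
#'
#' Parsing is case-sensitive by default; when the whole string is uniformly
#' upper- or lowercase, or `options$force_case_insensitive` is set,
#' capitalization carries no signal and components are recapitalized to
#' their canonical form afterwards (see [recapitalize()]).
#'
#' The dotted single letters `"v."`, `"f."` (always) and `"s."`, `"c."`
#' (only when enabled through `options$rank_aliases`) can be either
#' authority parts (e.g. filius in `"L. f."`) or rank indicators. They are
#' resolved by pattern rules: an author token before and an author-like
#' token after mean authority; an epithet-like token after, with no author
#' before, means rank indicator. When the signals conflict or are absent
#' the token is taken as a rank indicator (or, with no usable epithet after
#' it, left in the authority) and the parse is flagged
#' `"ambiguous_rank_token"` so the matcher can re-examine it after the
#' species-level match.
#'
#' @param normalized A single normalized name string (see
#'   [normalize_string()]).
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @return An object of class `parsed_name`: a list with fields `genus`,
#'   `genus_phonetic`, `species_epithet`, `species_phonetic`,
#'   `species_authority`, `infra` (list of up to two parts, each with
#'   `rank`, `rank_token`, `epithet`, `epithet_phonetic`, `authority`),
#'   `parse_flag`, `ambiguous_token`, `case_insensitive`, `normalized`.
#' @examples
#' p <- parse_name("Achillea millefolium L. subsp. sudetica (Opiz) Oborny")
#' p$genus
#' p$infra[[1]]$epithet
#' @export
parse_name <- function(normalized, options = NULL) {
  options <- as_match_options(options)
  .parse_tokens(normalized, options, force_authority_idx = NA_integer_)
}

.parse_tokens <- function(normalized, options, force_authority_idx) {
  stopifnot(is.character(normalized), length(normalized) == 1L)
  s <- trimws(normalized)
  if (!nzchar(s)) stop("cannot parse an empty name string", call. = FALSE)
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("cannot parse an empty name string", call. = FALSE)

  alpha <- gsub("[^A-Za-z]", "", s)
  uniform <- nzchar(alpha) && (alpha == toupper(alpha) || alpha == tolower(alpha))
  ci <- options$force_case_insensitive || uniform

  if (!grepl("^[A-Za-z]", toks[1L])) {
    stop("no plausible genus token at the start of: ", sQuote(s), call. = FALSE)
  }
  genus <- toks[1L]

  species <- ""
  i <- 2L
  if (length(toks) >= 2L && .is_epithet_like(toks[2L])) {
    species <- toks[2L]
    i <- 3L
  }

  infra <- list()
  species_authority <- character(0)
  parse_flag <- "clean"
  ambiguous_token <- ""
  ambiguous_idx <- NA_integer_
  amb_letters <- .ambiguous_letters(options)

  append_auth <- function(tok) {
    if (length(infra) == 0L) {
      species_authority <<- c(species_authority, tok)
    } else {
      k <- length(infra)
      infra[[k]]$authority <<- c(infra[[k]]$authority, tok)
    }
  }
  open_infra <- function(rank, rank_token, epithet) {
    infra[[length(infra) + 1L]] <<- list(
      rank = rank, rank_token = rank_token,
      epithet = epithet, authority = character(0))
  }

  n <- length(toks)
  while (i <= n) {
    tok <- toks[i]
    nxt <- if (i < n) toks[i + 1L] else ""
    nxt_epithet <- nzchar(nxt) && .is_epithet_like(nxt)

    if (grepl("^[A-Za-z]\\.$", tok) &&
        tolower(substr(tok, 1L, 1L)) %in% names(.AMBIGUOUS_RANK)) {
      letter <- tolower(substr(tok, 1L, 1L))
      enabled <- letter %in% amb_letters
      if (!enabled || identical(i, force_authority_idx)) {
        # never a rank indicator here: plain authority part
        append_auth(tok)
        i <- i + 1L
        next
      }
      prev_author <- i > 2L && .is_author_token(toks[i - 1L], ci)
      nxt_author <- nzchar(nxt) && grepl("[.()]", nxt)
      rank <- .AMBIGUOUS_RANK[[letter]]
      if (!nxt_epithet) {
        # no epithet can follow: stays in the authority; flag unless the
        # context is clearly an author sequence (author before, author after)
        append_auth(tok)
        if (!(prev_author && nxt_author)) {
          parse_flag <- "ambiguous_rank_token"
          ambiguous_token <- tok
          ambiguous_idx <- i
        }
        i <- i + 1L
        next
      }
      # an epithet-like token follows
      if (!ci && prev_author && grepl("^[A-Z]", nxt)) {
        # author before, capitalized word after: filius-style authority
        append_auth(tok)
        i <- i + 1L
        next
      }
      if (prev_author) {
        # conflicting signals: default to rank indicator, flag for re-check
        parse_flag <- "ambiguous_rank_token"
        ambiguous_token <- tok
        ambiguous_idx <- i
      } else if (ci && i > 2L) {
        # uniform case: capitalization signal unavailable; flag unless the
        # token directly follows the species epithet (no author could
        # precede it there)
        prev_bare <- .is_epithet_like(toks[i - 1L])
        if (!prev_bare) {
          parse_flag <- "ambiguous_rank_token"
          ambiguous_token <- tok
          ambiguous_idx <- i
        }
      }
      if (length(infra) >= 2L) {
        append_auth(tok)
        append_auth(nxt)
      } else {
        open_infra(rank, tok, nxt)
      }
      i <- i + 2L
      next
    }

    rank <- if (grepl("^[A-Za-z]", tok)) canonical_rank(tok, options) else NA_character_
    if (!is.na(rank) && nxt_epithet && !identical(i, force_authority_idx)) {
      if (length(infra) >= 2L) {
        append_auth(tok)
        append_auth(nxt)
      } else {
        open_infra(rank, tok, nxt)
      }
      i <- i + 2L
      next
    }

    append_auth(tok)
    i <- i + 1L
  }

  parsed <- structure(list(
    genus = genus,
    genus_phonetic = "",
    species_epithet = species,
    species_phonetic = "",
    species_authority = paste(species_authority, collapse = " "),
    infra = lapply(infra, function(p) {
      list(rank = p$rank, rank_token = p$rank_token, epithet = p$epithet,
           epithet_phonetic = "", authority = paste(p$authority, collapse = " "))
    }),
    parse_flag = parse_flag,
    ambiguous_token = ambiguous_token,
    ambiguous_token_index = ambiguous_idx,
    case_insensitive = ci,
    normalized = s
  ), class = "parsed_name")
  recapitalize(parsed)
}

#' Repair capitalization of a parsed name
#'
#' Puts the genus in initial-capital form and the epithets in lowercase;
#' authority strings are preserved verbatim, except in case-insensitive
#' mode where each authority token is title-cased (`"(opiz) oborny"` ->
#' `"(Opiz) Oborny"`). Phonetic keys are (re)computed from the repaired
#' components. Idempotent.
#'
#' @param parsed A `parsed_name` object.
#' @return The repaired `parsed_name`.
#' @examples
#' p <- parse_name("ACHILLEA MILLEFOLIUM L.")
#' p$genus # "Achillea"
#' @export
recapitalize <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_name"))
  cap1 <- function(x) {
    if (!nzchar(x)) return(x)
    paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
  }
  title_tokens <- function(x) {
    if (!nzchar(x)) return(x)
    toks <- strsplit(x, " ", fixed = TRUE)[[1]]
    toks <- vapply(toks, function(t) {
      m <- regexpr("[A-Za-z]", t)
      if (m > 0L) {
        substr(t, m, m) <- toupper(substr(t, m, m))
      }
      t
    }, character(1L))
    paste(toks, collapse = " ")
  }
  parsed$genus <- cap1(parsed$genus)
  parsed$species_epithet <- tolower(parsed$species_epithet)
  if (parsed$case_insensitive) {
    parsed$species_authority <- title_tokens(tolower(parsed$species_authority))
  }
  parsed$genus_phonetic <- .phon(parsed$genus)
  parsed$species_phonetic <- .phon(parsed$species_epithet)
  parsed$infra <- lapply(parsed$infra, function(p) {
    p$epithet <- tolower(p$epithet)
    if (parsed$case_insensitive) {
      p$rank_token <- tolower(p$rank_token)
      p$authority <- title_tokens(tolower(p$authority))
    }
    p$epithet_phonetic <- .phon(p$epithet)
    p
  })
  parsed
}

#' Reassemble a parsed name into a single string
#'
#' Joins genus, species epithet, species authority and the infraspecific
#' parts with single blanks. Up to capitalization repairs, this reproduces
#' the normalized input the name was parsed from.
#'
#' @param parsed A `parsed_name` object.
#' @return A single character string.
#' @export
reassemble_name <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_name"))
  parts <- c(parsed$genus, parsed$species_epithet, parsed$species_authority)
  for (p in parsed$infra) {
    parts <- c(parts, p$rank_token, p$epithet, p$authority)
  }
  paste(parts[nzchar(parts)], collapse = " ")
}

#' @export
print.parsed_name <- function(x, ...) {
  cat("<parsed_name> ", reassemble_name(x), "\n", sep = "")
  cat("  genus:   ", x$genus, " [", x$genus_phonetic, "]\n", sep = "")
  if (nzchar(x$species_epithet)) {
    cat("  species: ", x$species_epithet, " [", x$species_phonetic, "]",
        if (nzchar(x$species_authority)) paste0("  auth: ", x$species_authority),
        "\n", sep = "")
  }
  for (p in x$infra) {
    cat("  ", p$rank, " (", p$rank_token, "): ", p$epithet,
        " [", p$epithet_phonetic, "]",
        if (nzchar(p$authority)) paste0("  auth: ", p$authority), "\n", sep = "")
  }
  if (x$parse_flag != "clean") {
    cat("  flag: ", x$parse_flag, " (", x$ambiguous_token, ")\n", sep = "")
  }
  invisible(x)
}
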