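# Candidate generation and scoring against the thesaurus.
#
# Three-stage search: genera first (orthographic MDLD cap OR phonetic key
# equality), then species epithets within surviving genera by the same dual
# test, then infraspecific epithets with the wrong-rank penalty. Authorities
# are scored separately by bigram similarity. A cheap vectorized Levenshtein
# (utils::adist) prefilter bounds the MDLD calls: mdld <= levenshtein and
# levenshtein <= 2 * mdld, so mdld <= cap is impossible once
# levenshtein > 2 * cap.

# exact MDLD for the candidate values where it can still be <= cap or where
# a phonetic hit forces scoring; returns integer vector with NA where not computed
.stage_eds <- function(x, cands, cap, block_limit, need_extra = logical(length(cands))) {
  if (length(cands) == 0L) return(integer(0))
  lev <- as.integer(utils::adist(x, cands))
  ld <- abs(nchar(cands) - nchar(x))
  eds <- rep(NA_integer_, length(cands))
  maybe <- (ld <= cap & lev <= 2L * cap) | need_extra
  # lev == 0 or 1 cannot be improved by a transposition
  direct <- maybe & lev <= 1L
  eds[direct] <- lev[direct]
  todo <- which(maybe & lev > 1L)
  for (i in todo) eds[i] <- mdld(x, cands[i], block_limit)
  eds
}

#' Match a parsed name against the thesaurus
#'
#' Runs the staged fuzzy search for one parsed input name and returns every
#' candidate whose components each pass at least one of the two tests
#' (orthographic: MDLD within the stage cap; phonetic: equal phonetic keys,
#' when phonetics are enabled) and whose returned score reaches
#' `options$threshold`.
#'
#' @param parsed A `parsed_name` (see [parse_name()]).
#' @param thesaurus A `thesaurus` (see [build_thesaurus()]).
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @return A data frame of candidates sorted by `returned_score`
#'   (descending, ties by `entry_id`): per component the MDLD distance
#'   (`*_ed`), score (`*_score`) and how it matched (`*_via`:
#'   `"orthographic"`, `"phonetic"` or `"both"`), plus `taxon_score`,
#'   `author_score` and `returned_score` (0-100). Zero rows when nothing
#'   qualifies.
#' @export
match_parsed_name <- function(parsed, thesaurus, options = NULL) {
  stopifnot(inherits(parsed, "parsed_name"), inherits(thesaurus, "thesaurus"))
  options <- as_match_options(options)
  e <- thesaurus$entries
  if (nrow(e) == 0L) return(.empty_candidates())

  phon_on <- options$phonetic_enabled
  blim <- options$mdld_block_limit

  # ---- stage 1: genera
  gen <- unique(data.frame(genus = e$genus, phon = e$genus_phon,
                           stringsAsFactors = FALSE))
  g_phon_ok <- phon_on & nzchar(parsed$genus_phonetic) &
    gen$phon == parsed$genus_phonetic
  g_ed <- .stage_eds(parsed$genus, gen$genus, options$genus_ed_cap, blim,
                     need_extra = g_phon_ok)
  g_ortho_ok <- !is.na(g_ed) & g_ed <= options$genus_ed_cap
  keep_gen <- g_ortho_ok | g_phon_ok
  if (!any(keep_gen)) return(.empty_candidates())
  gen <- gen[keep_gen, , drop = FALSE]
  gen$ed <- g_ed[keep_gen]
  gen$ortho <- g_ortho_ok[keep_gen]
  gen$phonhit <- g_phon_ok[keep_gen]

  cand <- e[e$genus %in% gen$genus, , drop = FALSE]
  gi <- match(cand$genus, gen$genus)
  cand$genus_ed <- gen$ed[gi]
  cand$genus_via <- .via(gen$ortho[gi], gen$phonhit[gi])
  # phonetic-only genus hits can have ED beyond the prefilter window
  nae <- is.na(cand$genus_ed)
  if (any(nae)) {
    cand$genus_ed[nae] <- vapply(cand$genus[nae],
                                 function(g) mdld(parsed$genus, g, blim), integer(1L))
  }

  # ---- stage 2: species epithets
  has_species <- nzchar(parsed$species_epithet)
  if (has_species) {
    sp <- unique(data.frame(species = cand$species, phon = cand$species_phon,
                            stringsAsFactors = FALSE))
    s_phon_ok <- phon_on & nzchar(parsed$species_phonetic) &
      sp$phon == parsed$species_phonetic
    s_ed <- .stage_eds(parsed$species_epithet, sp$species,
                       options$epithet_ed_cap, blim, need_extra = s_phon_ok)
    s_ortho_ok <- !is.na(s_ed) & s_ed <= options$epithet_ed_cap
    keep_sp <- s_ortho_ok | s_phon_ok
    sp <- sp[keep_sp, , drop = FALSE]
    sp$ed <- s_ed[keep_sp]
    sp$ortho <- s_ortho_ok[keep_sp]
    sp$phonhit <- s_phon_ok[keep_sp]
    cand <- cand[cand$species %in% sp$species, , drop = FALSE]
    if (nrow(cand) == 0L) return(.empty_candidates())
    si <- match(cand$species, sp$species)
    cand$species_ed <- sp$ed[si]
    cand$species_via <- .via(sp$ortho[si], sp$phonhit[si])
    nae <- is.na(cand$species_ed)
    if (any(nae)) {
      cand$species_ed[nae] <- vapply(
        cand$species[nae],
        function(s) mdld(parsed$species_epithet, s, blim), integer(1L))
    }
  } else {
    cand$species_ed <- NA_integer_
    cand$species_via <- NA_character_
  }

  # ---- stage 3: infraspecific epithets
  depth_in <- length(parsed$infra)
  n <- nrow(cand)
  inf_ed <- matrix(NA_integer_, n, 2L)
  inf_score <- matrix(NA_real_, n, 2L)
  inf_via <- matrix(NA_character_, n, 2L)
  inf_pen <- matrix(FALSE, n, 2L)
  drop_row <- rep(FALSE, n)
  for (k in 1:2) {
    ep_col <- paste0("infra", k, "_epithet")
    ph_col <- paste0("infra", k, "_phon")
    rk_col <- paste0("infra", k, "_rank")
    in_has <- depth_in >= k
    cand_has <- nzchar(cand[[ep_col]])
    if (in_has) {
      ie <- parsed$infra[[k]]
      rows <- which(cand_has)
      if (length(rows) > 0L) {
        ue <- unique(data.frame(ep = cand[[ep_col]][rows],
                                phon = cand[[ph_col]][rows],
                                stringsAsFactors = FALSE))
        u_phon_ok <- phon_on & nzchar(ie$epithet_phonetic) &
          ue$phon == ie$epithet_phonetic
        u_ed <- .stage_eds(ie$epithet, ue$ep, options$epithet_ed_cap, blim,
                           need_extra = u_phon_ok)
        u_ortho_ok <- !is.na(u_ed) & u_ed <= options$epithet_ed_cap
        ui <- match(cand[[ep_col]][rows], ue$ep)
        ok <- u_ortho_ok[ui] | u_phon_ok[ui]
        drop_row[rows[!ok]] <- TRUE
        okrows <- rows[ok]
        eds <- u_ed[ui][ok]
        miss <- is.na(eds)
        if (any(miss)) {
          eds[miss] <- vapply(cand[[ep_col]][okrows][miss],
                              function(s) mdld(ie$epithet, s, blim), integer(1L))
        }
        inf_ed[okrows, k] <- eds
        inf_via[okrows, k] <- .via(u_ortho_ok[ui][ok], u_phon_ok[ui][ok])
        base <- vapply(seq_along(okrows), function(j) {
          component_score(eds[j], nchar(ie$epithet),
                          nchar(cand[[ep_col]][okrows[j]]))
        }, numeric(1L))
        pen <- vapply(okrows, function(r) {
          apply_rank_penalty(1, ie$rank, cand[[rk_col]][r]) < 1
        }, logical(1L))
        inf_pen[okrows, k] <- pen
        inf_score[okrows, k] <- ifelse(pen, pmax(base - 0.3, 0), base)
      }
      # candidate lacks this level: unmatched level scores 0, candidate kept
      inf_score[!cand_has, k] <- 0
    } else {
      # input lacks the level; candidates that have it score 0 there
      inf_score[cand_has, k] <- 0
    }
  }
  cand <- cand[!drop_row, , drop = FALSE]
  inf_ed <- inf_ed[!drop_row, , drop = FALSE]
  inf_score <- inf_score[!drop_row, , drop = FALSE]
  inf_via <- inf_via[!drop_row, , drop = FALSE]
  inf_pen <- inf_pen[!drop_row, , drop = FALSE]
  if (nrow(cand) == 0L) return(.empty_candidates())

  # ---- scores
  g_score <- vapply(seq_len(nrow(cand)), function(i) {
    component_score(cand$genus_ed[i], nchar(parsed$genus), nchar(cand$genus[i]))
  }, numeric(1L))
  if (has_species) {
    s_score <- vapply(seq_len(nrow(cand)), function(i) {
      component_score(cand$species_ed[i], nchar(parsed$species_epithet),
                      nchar(cand$species[i]))
    }, numeric(1L))
  } else {
    s_score <- rep(NA_real_, nrow(cand))
  }

  in_auth <- trimws(paste(parsed$species_authority,
                          paste(vapply(parsed$infra, `[[`, "", "authority"),
                                collapse = " ")))
  cand_auth <- trimws(paste(cand$species_auth, cand$infra1_auth, cand$infra2_auth))
  a_score <- vapply(cand_auth, function(ca) author_score(in_auth, ca), numeric(1L),
                    USE.NAMES = FALSE)

  t_score <- vapply(seq_len(nrow(cand)), function(i) {
    comps <- c(g_score[i], if (has_species) s_score[i],
               inf_score[i, !is.na(inf_score[i, ])])
    taxon_score(comps)
  }, numeric(1L))
  r_score <- returned_score_vec(t_score, a_score)

  out <- data.frame(
    entry_id = cand$entry_id, full_name = cand$full_name,
    status = cand$status, accepted_id = cand$accepted_id,
    genus_ed = cand$genus_ed, genus_score = g_score, genus_via = cand$genus_via,
    species_ed = cand$species_ed, species_score = s_score,
    species_via = cand$species_via,
    infra1_ed = inf_ed[, 1L], infra1_score = inf_score[, 1L],
    infra1_via = inf_via[, 1L], infra1_penalty = inf_pen[, 1L],
    infra2_ed = inf_ed[, 2L], infra2_score = inf_score[, 2L],
    infra2_via = inf_via[, 2L], infra2_penalty = inf_pen[, 2L],
    taxon_score = t_score, author_score = a_score, returned_score = r_score,
    stringsAsFactors = FALSE)
  out <- out[out$returned_score >= options$threshold, , drop = FALSE]
  out <- out[order(-out$returned_score, out$entry_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

returned_score_vec <- function(t, a) (t * 0.9 + a * 0.1) * 100

.via <- function(ortho, phon) {
  ifelse(ortho & phon, "both", ifelse(ortho, "orthographic", "phonetic"))
}

.empty_candidates <- function() {
  data.frame(
    entry_id = integer(0), full_name = character(0), status = character(0),
    accepted_id = integer(0),
    genus_ed = integer(0), genus_score = numeric(0), genus_via = character(0),
    species_ed = integer(0), species_score = numeric(0), species_via = character(0),
    infra1_ed = integer(0), infra1_score = numeric(0), infra1_via = character(0),
    infra1_penalty = logical(0),
    infra2_ed = integer(0), infra2_score = numeric(0), infra2_via = character(0),
    infra2_penalty = logical(0),
    taxon_score = numeric(0), author_score = numeric(0),
    returned_score = numeric(0), stringsAsFactors = FALSE)
}

#' Re-examine a flagged parse after the species-level match
#'
#' When the parser flagged an ambiguous single-letter token (see
#' [parse_name()]) and the species-level match gives no good infraspecific
#' hit (best infraspecific ED >= 2, or none at all), the flagged token is
#' checked against the authorities of the surviving candidates: if (a) the
#' token occurs in at least one surviving candidate's authority and (b) the
#' word following it in the input equals the word following it in that
#' authority — or starts with the same letter at MDLD distance 1 — the
#' token is reassigned to the authority and the input is re-parsed.
#' Otherwise the parse is returned unchanged.
#'
#' @param parsed A flagged `parsed_name`.
#' @param survivors Candidate data frame from [match_parsed_name()] (the
#'   species-level survivors).
#' @param thesaurus The `thesaurus` the candidates come from.
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @return A `parsed_name`: re-parsed when the verification succeeded, the
#'   input `parsed` otherwise.
#' @export
reparse_authority_check <- function(parsed, survivors, thesaurus, options = NULL) {
  stopifnot(inherits(parsed, "parsed_name"))
  options <- as_match_options(options)
  if (parsed$parse_flag != "ambiguous_rank_token") return(parsed)
  if (nrow(survivors) == 0L) return(parsed)

  # trigger: best infraspecific ED >= 2, or no infraspecific-level match
  infra_eds <- c(survivors$infra1_ed, survivors$infra2_ed)
  infra_eds <- infra_eds[!is.na(infra_eds)]
  if (length(infra_eds) > 0L && min(infra_eds) < 2L) return(parsed)

  tok <- tolower(parsed$ambiguous_token)
  in_toks <- strsplit(parsed$normalized, " ", fixed = TRUE)[[1]]
  in_toks <- in_toks[nzchar(in_toks)]
  pos <- parsed$ambiguous_token_index
  if (is.na(pos) || pos >= length(in_toks)) return(parsed)
  in_next <- tolower(in_toks[pos + 1L])

  e <- thesaurus$entries
  rows <- match(survivors$entry_id, e$entry_id)
  for (r in rows) {
    auth <- trimws(paste(e$species_auth[r], e$infra1_auth[r], e$infra2_auth[r]))
    if (!nzchar(auth)) next
    atoks <- strsplit(tolower(auth), " ", fixed = TRUE)[[1]]
    atoks <- atoks[nzchar(atoks)]
    hits <- which(atoks == tok)
    for (h in hits) {
      if (h >= length(atoks)) next
      ref_next <- atoks[h + 1L]
      same <- in_next == ref_next
      near <- substr(in_next, 1L, 1L) == substr(ref_next, 1L, 1L) &&
        mdld(in_next, ref_next, options$mdld_block_limit) == 1L
      if (same || near) {
        return(.parse_tokens(parsed$normalized, options,
                             force_authority_idx = pos))
      }
    }
  }
  parsed
}

#' Classify the match outcome for one input name
#'
#' `exact` when the normalized input equals a reference full name (the
#' pre-processing short-circuit); `none` when no candidate reached the
#' threshold; `unambiguous` when the best candidate is alone or leads the
#' runner-up by at least `options$ambiguity_margin` returned-score points;
#' `ambiguous` otherwise (all surviving candidates are retained for user
#' choice). A match on a synonym entry is resolved to its accepted name.
#'
#' @param candidates Candidate data frame from [match_parsed_name()].
#' @param normalized The normalized input string.
#' @param thesaurus The `thesaurus` matched against.
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @param raw_input The raw input string (for reporting; defaults to
#'   `normalized`).
#' @return An object of class `match_result`: list with `raw_input`,
#'   `normalized`, `status`, `candidates`, `chosen` (entry id or `NA`),
#'   `accepted_name`, `synonym_name`, `score`.
#' @export
classify_result <- function(candidates, normalized, thesaurus, options = NULL,
                            raw_input = normalized) {
  options <- as_match_options(options)
  e <- thesaurus$entries
  # pre-processing exact match
  ids <- .index_get(thesaurus$name_index, normalized)
  if (length(ids) == 0L && options$force_case_insensitive && nrow(e) > 0L) {
    ids <- e$entry_id[tolower(e$normalized) == tolower(normalized)]
  }
  if (length(ids) > 0L) {
    id <- min(ids)
    return(.finish_result(raw_input, normalized, "exact", candidates, id, 100,
                          thesaurus))
  }
  if (nrow(candidates) == 0L) {
    return(.finish_result(raw_input, normalized, "none", candidates,
                          NA_integer_, 0, thesaurus))
  }
  top <- candidates$returned_score[1L]
  runner <- if (nrow(candidates) >= 2L) candidates$returned_score[2L] else -Inf
  status <- if (nrow(candidates) == 1L ||
                top - runner >= options$ambiguity_margin) "unambiguous" else "ambiguous"
  .finish_result(raw_input, normalized, status, candidates,
                 candidates$entry_id[1L], top, thesaurus)
}

.finish_result <- function(raw_input, normalized, status, candidates, chosen,
                           score, thesaurus) {
  accepted_name <- ""
  synonym_name <- ""
  if (!is.na(chosen)) {
    e <- thesaurus$entries
    i <- match(chosen, e$entry_id)
    if (e$status[i] == "synonym") {
      synonym_name <- e$full_name[i]
      accepted_name <- e$full_name[match(e$accepted_id[i], e$entry_id)]
    } else {
      accepted_name <- e$full_name[i]
    }
  }
  structure(list(
    raw_input = raw_input, normalized = normalized, status = status,
    candidates = candidates, chosen = chosen,
    accepted_name = accepted_name, synonym_name = synonym_name,
    score = score
  ), class = "match_result")
}

#' Match one raw name through the full pipeline
#'
#' Normalization, exact pre-processing, parsing (with the post-match
#' re-parse verification for flagged names), staged fuzzy matching and
#' classification, in one call.
#'
#' @param raw A single raw name string.
#' @param thesaurus A `thesaurus`.
#' @param options A [match_options()] object (or `NULL` for defaults).
#' @return A `match_result` (see [classify_result()]).
#' @examples
#' rows <- data.frame(full_name = "Achillea millefolium L.",
#'                    status = "accepted", accepted_ref = "")
#' th <- build_thesaurus(rows)
#' match_name("Achillea milefolius L.", th)$status
#' @export
match_name <- function(raw, thesaurus, options = NULL) {
  options <- as_match_options(options)
  normalized <- normalize_string(raw, cfr_alias = options$cfr_alias)
  if (!nzchar(normalized)) {
    res <- .finish_result(raw, normalized, "none", .empty_candidates(),
                          NA_integer_, 0, thesaurus)
    res$note <- "empty after normalization"
    return(res)
  }
  # pre-processing: exact hit needs no parsing
  ids <- .index_get(thesaurus$name_index, normalized)
  if (length(ids) == 0L && options$force_case_insensitive &&
      nrow(thesaurus$entries) > 0L) {
    e <- thesaurus$entries
    ids <- e$entry_id[tolower(e$normalized) == tolower(normalized)]
  }
  if (length(ids) > 0L) {
    return(.finish_result(raw, normalized, "exact", .empty_candidates(),
                          min(ids), 100, thesaurus))
  }
  parsed <- tryCatch(parse_name(normalized, options), error = function(e) e)
  if (inherits(parsed, "error")) {
    res <- .finish_result(raw, normalized, "none", .empty_candidates(),
                          NA_integer_, 0, thesaurus)
    res$note <- conditionMessage(parsed)
    return(res)
  }
  if (parsed$parse_flag == "ambiguous_rank_token") {
    # the verification looks at everything that passed the species-level
    # match, not just what survives the user threshold
    relaxed <- options
    relaxed$threshold <- 1L
    survivors <- match_parsed_name(parsed, thesaurus, relaxed)
    parsed <- reparse_authority_check(parsed, survivors, thesaurus, options)
  }
  cands <- match_parsed_name(parsed, thesaurus, options)
  classify_result(cands, normalized, thesaurus, options, raw_input = raw)
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", sQuote(x$raw_input), ": ", x$status, sep = "")
  if (!is.na(x$chosen)) {
    cat(" -> ", x$accepted_name,
        if (nzchar(x$synonym_name)) paste0(" (via synonym ", x$synonym_name, ")"),
        sprintf(" [%.2f]", x$score), sep = "")
  }
  cat("\n")
  if (x$status == "ambiguous") {
    cat("  ", nrow(x$candidates), " candidates within the ambiguity margin\n",
        sep = "")
  }
  invisible(x)
}
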