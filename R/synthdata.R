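# Seeded synthetic checklists and corrupted query lists.
#
# Pseudo-Latin names are composed from syllable inventories (no real
# checklist content), preserving the length statistics of botanical
# epithets (mean 8-11 characters). Everything is reproducible from the
# seed, and every corruption is logged against its source entry so
# recovery experiments are closed-loop.

.SYL_START <- c("ba", "ca", "da", "fa", "ga", "la", "ma", "na", "pa", "ra",
                "sa", "ta", "va", "ce", "de", "le", "me", "ne", "pe", "re",
                "se", "te", "ve", "ci", "di", "li", "mi", "ni", "pi", "ri",
                "si", "ti", "vi", "co", "do", "lo", "mo", "no", "po", "ro")
.SYL_END <- c("tus", "nus", "rus", "lis", "ris", "tum", "num", "rum",
              "ica", "ina", "osa", "ata", "ella", "ifer", "oides", "ensis")
.AUTH_POOL <- c("L.", "Mill.", "Lam.", "Scop.", "Huds.", "Ten.", "Willd.",
                "(Opiz) Oborny", "Bernh. ex Schrank & Mart.", "(L.) DC.",
                "Willd. f.", "(Mill.) Sweet", "L. f.")
.RANK_POOL <- c("subsp.", "var.", "f.")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

.make_word <- function(n_syl) {
  paste0(paste(sample(.SYL_START, n_syl - 1L, replace = TRUE), collapse = ""),
         sample(.SYL_END, 1L))
}

#' Generate a seeded synthetic checklist
#'
#' Builds `n_accepted` accepted names (pseudo-Latin binomials with
#' authorities; a fraction gets one infraspecific level) plus
#' `round(n_accepted * synonym_fraction)` synonyms pointing at uniformly
#' chosen accepted entries. Full names are unique by construction
#' (regenerated on collision). The authority pool deliberately includes
#' forms containing `"f."` (filius) to exercise the rank/authority
#' ambiguity; names carrying an `"f."` token are marked
#' `ambiguous_expected` in the manifest.
#'
#' @param n_accepted Number of accepted names (>= 1).
#' @param synonym_fraction Fraction of `n_accepted` emitted as synonyms
#'   (default 0.3).
#' @param infra_fraction Fraction of accepted names given an infraspecific
#'   level (default 0.2).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return An object of class `synthetic_manifest`: list with `seed`,
#'   `rows` (the checklist data frame `full_name`/`status`/`accepted_ref`
#'   that [build_thesaurus()] consumes), `components` (per-name generated
#'   components, including `ambiguous_expected`) and `corruptions` (empty
#'   log, filled by [corrupt_name()] users).
#' @examples
#' m <- generate_checklist(10, synonym_fraction = 0.3, seed = 1)
#' nrow(m$rows)
#' @export
generate_checklist <- function(n_accepted, synonym_fraction = 0.3,
                               infra_fraction = 0.2, seed = 1L) {
  stopifnot(n_accepted >= 1, synonym_fraction >= 0, synonym_fraction <= 1,
            infra_fraction >= 0, infra_fraction <= 1)
  .with_seed(seed, {
    n_genera <- max(3L, ceiling(n_accepted / 5))
    genera <- character(0)
    while (length(genera) < n_genera) {
      g <- .make_word(sample(2:3, 1L))
      g <- paste0(toupper(substr(g, 1L, 1L)), substr(g, 2L, nchar(g)))
      if (!g %in% genera) genera <- c(genera, g)
    }
    n_syn <- round(n_accepted * synonym_fraction)
    n_total <- n_accepted + n_syn
    comp <- data.frame(
      full_name = character(n_total), status = character(n_total),
      accepted_ref = character(n_total), genus = character(n_total),
      species = character(n_total), authority = character(n_total),
      infra_token = character(n_total), infra_epithet = character(n_total),
      ambiguous_expected = logical(n_total), stringsAsFactors = FALSE)
    seen <- character(0)
    for (i in seq_len(n_total)) {
      repeat {
        genus <- sample(genera, 1L)
        species <- .make_word(sample(3:4, 1L))
        auth <- sample(.AUTH_POOL, 1L)
        has_infra <- i <= n_accepted && stats::runif(1L) < infra_fraction
        if (has_infra) {
          itok <- sample(.RANK_POOL, 1L)
          iep <- if (stats::runif(1L) < 0.3) species else .make_word(sample(3:4, 1L))
          full <- paste(genus, species, auth, itok, iep)
        } else {
          itok <- ""
          iep <- ""
          full <- paste(genus, species, auth)
        }
        if (!full %in% seen) break
      }
      seen <- c(seen, full)
      comp$full_name[i] <- full
      comp$genus[i] <- genus
      comp$species[i] <- species
      comp$authority[i] <- auth
      comp$infra_token[i] <- itok
      comp$infra_epithet[i] <- iep
      comp$ambiguous_expected[i] <- grepl("(^| )f\\.( |$)", full)
      if (i <= n_accepted) {
        comp$status[i] <- "accepted"
        comp$accepted_ref[i] <- ""
      } else {
        comp$status[i] <- "synonym"
        comp$accepted_ref[i] <- comp$full_name[sample.int(n_accepted, 1L)]
      }
    }
    structure(list(
      seed = as.integer(seed),
      rows = comp[, c("full_name", "status", "accepted_ref")],
      components = comp,
      corruptions = data.frame(name = character(0), source = character(0),
                               op = character(0), detail = character(0),
                               stringsAsFactors = FALSE)
    ), class = "synthetic_manifest")
  })
}

#' Corrupt a name with a logged set of edits
#'
#' Applies exactly `n_edits` seeded edit operations to the name. Character
#' edits (`substitution`, `insertion`, `deletion`, `transposition`) hit
#' random positions inside epithet tokens only — blanks are never touched,
#' mirroring the constraint real typos in name lists obey. `case_fold`
#' uppercases the whole string; `rank_swap` replaces the rank indicator
#' with a wrong or nonstandard alias.
#'
#' @param name The source name string.
#' @param n_edits Number of edits (>= 1).
#' @param edit_kinds Character vector drawn from `substitution`,
#'   `insertion`, `deletion`, `transposition`, `case_fold`, `rank_swap`.
#' @param seed Integer seed.
#' @return List with `corrupted` (the edited string) and `log` (data frame
#'   of the operations applied: op, token, position, before, after).
#' @examples
#' corrupt_name("Achillea millefolium", 1, "substitution", seed = 3)$corrupted
#' @export
corrupt_name <- function(name, n_edits = 1L,
                         edit_kinds = c("substitution"), seed = 1L) {
  kinds_ok <- c("substitution", "insertion", "deletion", "transposition",
                "case_fold", "rank_swap")
  stopifnot(is.character(name), length(name) == 1L, n_edits >= 1L,
            all(edit_kinds %in% kinds_ok))
  .with_seed(seed, {
    cur <- name
    log <- list()
    for (step in seq_len(n_edits)) {
      kind <- if (length(edit_kinds) == 1L) edit_kinds else sample(edit_kinds, 1L)
      toks <- strsplit(cur, " ", fixed = TRUE)[[1]]
      # epithet tokens: bare alphabetic, after the genus, not rank indicators
      is_ep <- grepl("^[A-Za-z-]+$", toks) & seq_along(toks) >= 2L &
        !vapply(toks, function(t) {
          !is.na(suppressWarnings(canonical_rank(t)))
        }, logical(1L))
      ep_idx <- which(is_ep)
      if (kind == "case_fold") {
        log[[step]] <- data.frame(op = kind, token = NA_integer_,
                                  position = NA_integer_, before = cur,
                                  after = toupper(cur), stringsAsFactors = FALSE)
        cur <- toupper(cur)
        next
      }
      if (kind == "rank_swap") {
        rk <- which(vapply(toks, function(t) {
          grepl("\\.$", t) && !is.na(suppressWarnings(canonical_rank(t)))
        }, logical(1L)))
        if (length(rk) == 0L) {
          stop("no rank indicator to swap in: ", sQuote(name), call. = FALSE)
        }
        pos <- rk[1L]
        alt <- setdiff(c("subsp.", "var.", "f.", "s.", "ssp", "varietas"),
                       toks[pos])
        new_tok <- sample(alt, 1L)
        log[[step]] <- data.frame(op = kind, token = pos, position = NA_integer_,
                                  before = toks[pos], after = new_tok,
                                  stringsAsFactors = FALSE)
        toks[pos] <- new_tok
        cur <- paste(toks, collapse = " ")
        next
      }
      if (length(ep_idx) == 0L) {
        stop("no epithet token to edit in: ", sQuote(name), call. = FALSE)
      }
      ti <- if (length(ep_idx) == 1L) ep_idx else sample(ep_idx, 1L)
      tok <- toks[ti]
      nc <- nchar(tok)
      if (kind == "deletion" && nc < 2L) {
        stop("token too short for a deletion in: ", sQuote(name), call. = FALSE)
      }
      if (kind == "transposition" && nc < 2L) {
        stop("token too short for a transposition in: ", sQuote(name),
             call. = FALSE)
      }
      new_tok <- switch(kind,
        substitution = {
          p <- sample.int(nc, 1L)
          old <- substr(tok, p, p)
          repl <- sample(setdiff(letters, tolower(old)), 1L)
          `substr<-`(tok, p, p, repl)
        },
        insertion = {
          p <- sample.int(nc + 1L, 1L)
          paste0(substr(tok, 1L, p - 1L), sample(letters, 1L),
                 substr(tok, p, nc))
        },
        deletion = {
          p <- sample.int(nc, 1L)
          paste0(substr(tok, 1L, p - 1L), substr(tok, p + 1L, nc))
        },
        transposition = {
          p <- sample.int(nc - 1L, 1L)
          paste0(substr(tok, 1L, p - 1L), substr(tok, p + 1L, p + 1L),
                 substr(tok, p, p), substr(tok, p + 2L, nc))
        })
      log[[step]] <- data.frame(op = kind, token = ti, position = NA_integer_,
                                before = tok, after = new_tok,
                                stringsAsFactors = FALSE)
      toks[ti] <- new_tok
      cur <- paste(toks, collapse = " ")
    }
    list(corrupted = cur, log = do.call(rbind, log))
  })
}

#' Build a profile query list emulating a heterogeneous real-world dataset
#'
#' Three canned profiles mirror common styles of digitized name lists:
#' profile `"A"` — names without authorities and `"s."` as the subspecies
#' indicator; profile `"B"` — names written entirely in uppercase;
#' profile `"C"` — names following the nomenclatural code verbatim. A
#' `corrupt_fraction` of the sampled names additionally receives one
#' seeded epithet substitution.
#'
#' @param manifest A `synthetic_manifest` from [generate_checklist()].
#' @param profile `"A"`, `"B"` or `"C"`.
#' @param n Number of names to draw (with replacement when `n` exceeds the
#'   checklist size; duplicates are legitimate in raw lists).
#' @param corrupt_fraction Fraction of drawn names given one substitution
#'   (default 0.2).
#' @param seed Integer seed.
#' @return Character vector of query names.
#' @export
synthetic_profile <- function(manifest, profile = c("A", "B", "C"), n,
                              corrupt_fraction = 0.2, seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(inherits(manifest, "synthetic_manifest"), n >= 1)
  comp <- manifest$components
  .with_seed(seed, {
    idx <- sample.int(nrow(comp), n, replace = n > nrow(comp))
    out <- vapply(idx, function(i) {
      if (profile == "A") {
        itok <- comp$infra_token[i]
        if (nzchar(itok)) {
          itok <- if (itok == "subsp.") "s." else itok
          paste(comp$genus[i], comp$species[i], itok, comp$infra_epithet[i])
        } else {
          paste(comp$genus[i], comp$species[i])
        }
      } else {
        comp$full_name[i]
      }
    }, character(1L))
    corrupt <- stats::runif(n) < corrupt_fraction
    for (j in which(corrupt)) {
      out[j] <- corrupt_name(out[j], 1L, "substitution",
                             seed = sample.int(.Machine$integer.max, 1L))$corrupted
    }
    if (profile == "B") out <- toupper(out)
    out
  })
}

#' @export
print.synthetic_manifest <- function(x, ...) {
  cat("<synthetic_manifest> seed ", x$seed, ": ",
      sum(x$rows$status == "accepted"), " accepted + ",
      sum(x$rows$status == "synonym"), " synonyms\n", sep = "")
  invisible(x)
}
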