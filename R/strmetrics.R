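#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions or substitutions
#' transforming `a` into `b`. Thin wrapper over [utils::adist()].
#'
#' @param a,b Character scalars.
#' @return Non-negative integer edit distance.
#' @examples
#' levenshtein("milefolius", "millefolium") # 2
#' levenshtein("canadsiens", "canadensis")  # 4
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  as.integer(utils::adist(a, b)[1L, 1L])
}

#' Modified Damerau-Levenshtein distance with block transpositions
#'
#' Edit distance extending [levenshtein()] with transpositions of two
#' adjacent blocks of equal length `k` (`1 <= k <= block_limit`), a swap of
#' two length-`k` blocks costing `k`. With `block_limit = 1` this is the
#' classic Damerau-Levenshtein (optimal string alignment) distance. The
#' distance is alignment-based: a transposed block is emitted as a unit and
#' never edited again.
#'
#' Misspellings that scramble letters are charged far less than by plain
#' Levenshtein: `"canadsiens"` vs `"canadensis"` costs 2 (one swap of the
#' adjacent blocks "si" and "en") instead of 4 substitutions.
#'
#' @param a,b Character scalars.
#' @param block_limit Maximum transposed block length (default 2).
#' @return Non-negative integer; always `<= levenshtein(a, b)`.
#' @examples
#' mdld("canadsiens", "canadensis") # 2
#' mdld("ab", "ba", block_limit = 1) # 1
#' @export
mdld <- function(a, b, block_limit = 2L) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  block_limit <- as.integer(block_limit)
  stopifnot(block_limit >= 1L)
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  m <- length(av)
  n <- length(bv)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  # (m+1) x (n+1) DP matrix, 1-based offsets
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1L] <- 0L:m
  d[1L, ] <- 0L:n
  for (i in seq_len(m)) {
    ai <- av[i]
    for (j in seq_len(n)) {
      cost <- if (ai == bv[j]) 0L else 1L
      best <- min(d[i, j] + cost, d[i, j + 1L] + 1L, d[i + 1L, j] + 1L)
      kmax <- min(block_limit, i %/% 2L, j %/% 2L)
      if (kmax >= 1L) {
        for (k in seq_len(kmax)) {
          # swap a's blocks [i-2k+1 .. i-k] [i-k+1 .. i] to match b's
          # [j-2k+1 .. j-k] [j-k+1 .. j]
          if (all(av[(i - 2L * k + 1L):(i - k)] == bv[(j - k + 1L):j]) &&
              all(av[(i - k + 1L):i] == bv[(j - 2L * k + 1L):(j - k)])) {
            cand <- d[i - 2L * k + 1L, j - 2L * k + 1L] + k
            if (cand < best) best <- cand
          }
        }
      }
      d[i + 1L, j + 1L] <- best
    }
  }
  as.integer(d[m + 1L, n + 1L])
}

#' Bigram (n-gram) similarity between authority strings
#'
#' Dice coefficient over the multisets of character bigrams of the two
#' strings after case-folding and removal of blanks and non-letters.
#' Author citations differ mostly in punctuation and abbreviation, so only
#' the letters carry signal. Equal strings (after case-folding and blank
#' removal) score 1 even when too short to yield a bigram.
#'
#' @param a,b Character scalars (possibly empty).
#' @return Similarity in `[0, 1]`.
#' @examples
#' ngram_similarity("(Opiz) Oborny", "(Opiz) Oborny") # 1
#' ngram_similarity("L.", "Mill.")                    # 0
#' @export
ngram_similarity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  fold <- function(x) tolower(gsub("[[:blank:]]+", "", x))
  fa <- fold(a)
  fb <- fold(b)
  if (!nzchar(fa) || !nzchar(fb)) return(0)
  if (fa == fb) return(1)
  ga <- .bigrams(gsub("[^a-z]+", "", fa))
  gb <- .bigrams(gsub("[^a-z]+", "", fb))
  if (length(ga) == 0L || length(gb) == 0L) return(0)
  # multiset intersection size
  ta <- table(ga)
  tb <- table(gb)
  shared <- intersect(names(ta), names(tb))
  ninter <- sum(pmin(ta[shared], tb[shared]))
  2 * ninter / (length(ga) + length(gb))
}

.bigrams <- function(x) {
  n <- nchar(x)
  if (n < 2L) return(character(0))
  substring(x, 1L:(n - 1L), 2L:n)
}

#' Phonetic key of a Latin epithet or genus name
#'
#' Uppercase canonical encoding under which common misspellings of Latin
#' botanical epithets collide. The first letter is preserved; in the
#' remainder, digraphs are folded first (AE -> I, IA -> A, OE -> I,
#' OI -> A), then H is dropped, vowels are folded (E -> I, O -> A, U -> I;
#' A and I are stable), consonants Z -> S and K -> C, and doubled letters
#' are collapsed. Idempotent on its own output.
#'
#' @param word A single alphabetic word (genus name or epithet).
#' @return Uppercase phonetic key.
#' @examples
#' phonetic_key("Huperzia") # "HIPIRSA"
#' phonetic_key("selago")   # "SILAGA"
#' @export
phonetic_key <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (!nzchar(word) || grepl("[^A-Za-z]", word)) {
    stop("phonetic_key() expects a single alphabetic word, got: ",
         deparse(word), call. = FALSE)
  }
  w <- toupper(word)
  head1 <- substr(w, 1L, 1L)
  rest <- substr(w, 2L, nchar(w))
  if (nzchar(rest)) {
    rest <- gsub("AE", "I", rest, fixed = TRUE)
    rest <- gsub("IA", "A", rest, fixed = TRUE)
    rest <- gsub("OE", "I", rest, fixed = TRUE)
    rest <- gsub("OI", "A", rest, fixed = TRUE)
    rest <- gsub("H", "", rest, fixed = TRUE)
    rest <- chartr("EOUZK", "IAISC", rest)
    # the vowel fold can mint fresh IA digraphs (e.g. EA -> IA); fold to a
    # fixpoint so the encoder is idempotent on its own output
    while (grepl("IA", rest, fixed = TRUE)) {
      rest <- gsub("IA", "A", rest, fixed = TRUE)
    }
  }
  key <- paste0(head1, rest)
  # collapse runs of the same letter
  gsub("(.)\\1+", "\\1", key)
}
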