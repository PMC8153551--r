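---
title: "Matching botanical names against a checklist: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching botanical names against a checklist: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomenmatch)
```

## The problem

Lists of plant names coming out of digitization projects — old floras,
herbarium labels, vegetation relevés — carry typos, outdated synonyms,
nonstandard rank indicators and inconsistent capitalization. `nomenmatch`
aligns such lists to a reference checklist of accepted names and synonyms,
and corrects free-text query strings to the nearest substring of a
reference name. This vignette explains the models behind both tools, the
tunable parameters, and the design choices made where more than one
reasonable reading existed.

## The list-matching pipeline

Every input name passes four stages.

**1. Normalization** (`normalize_string()`): special characters are
removed (underscores become blanks so `Genus_species` stays two tokens),
digits are dropped, diacritics are transliterated to ASCII, a blank is
guaranteed after every dot, the uncertainty tokens `cf.` and `aff.` are
deleted, and blank runs are collapsed. The function is total and
idempotent, and its output alphabet is restricted to the characters a
parsed name can legally contain. One visible consequence of the
blank-after-dot rule is that `(L.)` normalizes to `(L. )`; since reference
names and inputs pass through the same normalizer, matching is unaffected.

**2. Pre-processing**: if the normalized string equals a reference name
verbatim, it is returned immediately with the maximum score of 100. No
parsing or fuzzy work happens for exact hits.

**3. Parsing** (`parse_name()`): the string is decomposed into genus,
species epithet, species authority, and up to two infraspecific parts
(rank indicator, epithet, authority). Parsing is case-sensitive by
default, because capitalization separates epithets from author names; when
the whole string is uniformly upper- or lowercase — or the user forces it
— the parser switches to a case-insensitive mode in which capitalization
carries no signal and components are recapitalized to canonical form
afterwards. Rank indicators are recognized through alias tables
(`subsp`/`ssp`/`subspecies`, `var`/`varietas`, `f`/`fo`/`forma`, `cv`),
case-insensitively, with or without the trailing dot, and with one
character of slack (`susp` still means subspecies). Fuzzy alias matching
is restricted to tokens of three or more characters: without that guard
every stray single letter would sit one edit away from `f` or `cv`.

The dotted single letters `v.` and `f.` (and `s.`/`c.`, which stand for
subspecies/cultivar only when the user enables them, since that usage is
rare) are genuinely ambiguous between rank indicators and authority parts
(`L. f.` is Linnaeus filius). The parser resolves them with context rules:
an author token before and an author-like token after mean authority; an
epithet-like token after, with no author before, means rank indicator.
When the signals conflict — author before *and* bare epithet after — the
token is provisionally taken as a rank indicator and the parse is flagged.
A flagged token with no usable epithet after it stays in the authority
(an infraspecific part without an epithet is not representable), still
flagged.

**4. Matching** (`match_parsed_name()`): candidates are found in three
stages — genera, then species epithets within surviving genera, then
infraspecific epithets. At each stage a component passes if it survives
*either* the orthographic test (block-transposition edit distance within
the stage cap) *or* the phonetic test (equal phonetic keys). Each
component then receives

$$\mathrm{ComponentScore} = 1 - \mathrm{ED}/\mathrm{maxED}$$

where ED is the block-transposition distance and maxED the length of the
longer of the two strings. An infraspecific component loses a flat 0.3
when its rank indicator disagrees with the reference (typing `var.` where
the checklist has `subsp.` turns a perfect 1.0 into 0.7); the penalty
floors at zero so component scores stay in $[0,1]$. The taxon score is the
arithmetic mean of the component scores, authorities are compared
separately with a bigram similarity, and the final user-facing score is

$$\mathrm{ReturnedScore} = (\mathrm{TaxonScore} \times 0.9 +
\mathrm{AuthorScore} \times 0.1) \times 100 .$$

For a flagged parse, a verification step runs after the species-level
match: if the flagged token occurs in the authority of a surviving
candidate and the word following it in the input matches the word
following it in that authority (equal, or same first letter at distance
1), the token is reassigned to the authority and the tail of the name is
re-parsed. The verification deliberately looks at all species-level
survivors, not only those above the user threshold.

### Classification

`exact` is decided in pre-processing. Otherwise a name is `none` when no
candidate reaches the score threshold, `unambiguous` when the best
candidate is alone or leads the runner-up by at least the ambiguity
margin, and `ambiguous` otherwise, with all surviving candidates kept for
the user. A match that lands on a synonym entry is resolved to its
accepted name; the batch CSV reports both.

## The string comparators

**Edit distance with block transpositions** (`mdld()`): classic
Levenshtein extended with transpositions of two adjacent blocks of equal
length $k \le$ `block_limit`, a swap costing $k$. This is what lets
`canadsiens` reach `canadensis` at cost 2 (swap `si`/`en`) instead of the
Levenshtein 4. The distance is alignment-based: a transposed block is
emitted as a unit and never edited again, which is the standard
formulation in taxonomic fuzzy matchers. The default `block_limit` of 2
covers the scrambles seen in practice; it is configurable upward.
Unequal-length block swaps are not supported — they would blur into
general block moves, whose minimal-cost computation is a different (and
much harder) problem.

**Phonetic encoder** (`phonetic_key()`): uppercase; first letter
preserved; in the remainder, digraphs are folded (AE→I, IA→A, OE→I,
OI→A), H is dropped, the unstable vowels are folded (E→I, O→A, U→I; A and
I are the sinks), Z→S, K→C, and doubled letters are collapsed. Because
the vowel fold can mint fresh `IA` digraphs (`EA` becomes `IA`), the `IA`
fold is applied to a fixpoint, making the encoder idempotent on its own
output — a property the matcher relies on when comparing keys with keys.
The rule table is pinned by tests to the two reference encodings
`Huperzia → HIPIRSA` and `selago → SILAGA`; any future refinement that
moves other encodings will be visible in the test suite.

**Authority similarity** (`ngram_similarity()`): Dice coefficient over
character bigrams. Author citations differ mostly in punctuation and
abbreviation conventions (`L.` vs `Linnaeus`, `(Opiz) Oborny` with or
without blanks), so bigrams are taken over the case-folded letters only;
strings equal after case-folding and blank removal score 1 outright.
Authorities absent on both sides agree perfectly (a bare binomial against
a bare binomial stays at 100); an authority present on exactly one side
scores 0 — the conservative reading, since nothing can be verified.

## The interactive query corrector

`nearest_query_match()` serves the search-box use case: the query may be
any substring of a name (`lantus alt`). If it does not occur verbatim in
any reference name, every window of length $|q|-1$ to $|q|+1$ of every
reference name is scored with a blank-locked edit distance in which a
blank never aligns to a non-blank and is never inserted or deleted. The
cheapest correction within `query_edit_cap` edits (default 2) wins; ties
go to the correction contained in the most reference entries, then
lexicographic. A vectorized plain-Levenshtein prefilter bounds the
windows that need the constrained dynamic program.

## Tunable parameters

| Option | Default | Meaning |
|---|---|---|
| `threshold` | 70 | minimum returned score; at 100 only exact matches survive |
| `ambiguity_margin` | 5 | lead (in score points) that makes the best candidate unambiguous |
| `phonetic_enabled` | `TRUE` | phonetic test alongside the orthographic one; disabling never adds candidates |
| `genus_ed_cap` | 2 | stage-1 orthographic cap on the genus distance |
| `epithet_ed_cap` | 3 | stage-2/3 orthographic cap on epithet distances |
| `mdld_block_limit` | 2 | longest transposable block |
| `query_edit_cap` | 2 | edit budget of the query corrector |
| `max_names` | 5000 | cap on distinct names per list |
| `force_case_insensitive` | `FALSE` | parse without capitalization signals |
| `rank_aliases` | empty | user rank indicators, e.g. `list(subspecies = "s.")` |

The 0.9/0.1 weighting and the 0.3 rank penalty are part of the scoring
model, not options. The stage caps are fixed rather than length-dependent:
at checklist scale (tens of thousands of names with epithets mostly 6–12
characters long) fixed caps of 2 and 3 keep the candidate sets small
without losing plausible matches, and they are exposed as options for
checklists with different length statistics. The ambiguity margin of 5
points is a documented choice — "ambiguous" needs an operational
definition once more than one candidate survives, and 5 points
distinguishes a one-edit difference from a near-tie at typical epithet
lengths. The default threshold of 70 admits roughly two edits across a
binomial's components while rejecting matches where a whole component has
collapsed.

## Degenerate inputs and tie-breaks

Unparseable list entries become `none` results with a note; unparseable
reference rows are quarantined with a reason and reported, never silently
dropped, so one bad row cannot sink a 24k-name build. Duplicate reference
full names keep the first occurrence with a warning (how real portals
store homonyms is not observable from outside; first-wins is
reproducible). Equal-score candidates order by entry id, so runs are
deterministic. When the input and a candidate disagree on the *presence*
of an infraspecific level, that level scores 0 and still enters the mean —
a conservative rule that prevents `Achillea millefolium` from outranking
`Achillea millefolium subsp. sudetica` matches of an infraspecific input,
while still letting the species-level entry appear.

## The synthetic generator

`generate_checklist()` composes pseudo-Latin names from syllable
inventories — no licensed checklist content ships with the package —
while preserving what matters for matching: epithet lengths around 8–11
characters, shared genera, authorities drawn from a pool that includes
parenthesized basionym authors and filius forms (`Willd. f.`, `L. f.`) to
exercise the rank/authority ambiguity, an infraspecific fraction, and
synonyms pointing at uniformly chosen accepted entries. `corrupt_name()`
applies a logged number of edits inside epithet tokens (blanks are never
touched), plus whole-string case folding and rank-indicator swaps, so
recovery experiments are closed-loop: the source of every corrupted name
is known. Three profile builders emulate common dataset styles: no
authorities with `s.` as the subspecies indicator (A), all uppercase (B),
and code-compliant (C).

What the generator does *not* emulate: real genera sharing long common
prefixes, hybrid formulas, abbreviation variants of the same author, and
the heavy-tailed frequency of a few large genera. Passing the synthetic
recovery tests therefore demonstrates the machinery works as specified,
not that any particular real-world accuracy will be achieved.

The test and acceptance runs use a 1000-entry checklist (500 accepted +
500 synonyms, seed 42) — synonyms make up about half of the reference
pool, mirroring the roughly 55% synonym share of the national vascular
checklist the tool is aimed at, as closely as a synonym fraction bounded
by 1.0 expresses — with 1000 single-substitution corruption trials, and a
1000-entry thesaurus for the query-corrector checks. The exhaustive
edit-distance validation enumerates all string pairs up to length 5 over
a three-letter alphabet against a brute-force edit-script search.

## Known limitations

* Hybrid signs (`×`), `sp.`/`spp.` placeholders and collector numbers
  (`s.n.`) are passed through untouched rather than interpreted.
* The second infraspecific authority is delimited purely positionally;
  exotic four-part names may parse their tails into the wrong authority.
* No nomenclatural validation is attempted: the parser classifies tokens,
  it does not check valid publication or author abbreviation standards.
* The within-genus scan is linear; for checklists far beyond ~10^5 names
  an indexed approximate-search structure would be the next step.
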