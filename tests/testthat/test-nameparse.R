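test_that("the infraspecific worked example parses into its six components", {
  p <- parse_name("Achillea millefolium L. subsp. sudetica (Opiz) Oborny")
  expect_identical(p$genus, "Achillea")
  expect_identical(p$species_epithet, "millefolium")
  expect_identical(p$species_authority, "L.")
  expect_length(p$infra, 1)
  expect_identical(p$infra[[1]]$rank, "subspecies")
  expect_identical(p$infra[[1]]$rank_token, "subsp.")
  expect_identical(p$infra[[1]]$epithet, "sudetica")
  expect_identical(p$infra[[1]]$authority, "(Opiz) Oborny")
  expect_identical(p$parse_flag, "clean")
})

test_that("rank indicators are recognized case-insensitively, dot-optionally, and with one typo", {
  expect_identical(canonical_rank("subsp."), "subspecies")
  expect_identical(canonical_rank("Subsp."), "subspecies")
  expect_identical(canonical_rank("susp"), "subspecies")
  expect_identical(canonical_rank("ssp"), "subspecies")
  expect_identical(canonical_rank("var."), "variety")
  expect_identical(canonical_rank("varietas"), "variety")
  expect_identical(canonical_rank("forma"), "form")
  expect_identical(canonical_rank("fo"), "form")
  expect_identical(canonical_rank("cv"), "cultivar")
  expect_identical(canonical_rank("grandiflora"), NA_character_)
  # short indicators never fuzzy-match: "x" is not one edit from "f"
  expect_identical(canonical_rank("x"), NA_character_)
})

test_that("user rank aliases are consulted first and equal-distance ties warn", {
  opts <- match_options(rank_aliases = list(subspecies = "s."))
  expect_identical(canonical_rank("s.", opts), "subspecies")
  expect_identical(canonical_rank("s."), NA_character_)
  tie <- match_options(rank_aliases = list(subspecies = "abc", variety = "abd"))
  expect_warning(r <- canonical_rank("abe", tie), "several ranks")
  expect_identical(r, NA_character_)
})

test_that("uniform-case input switches to case-insensitive parsing with recapitalization", {
  p <- parse_name("ACHILLEA MILLEFOLIUM L.")
  expect_true(p$case_insensitive)
  expect_identical(p$genus, "Achillea")
  expect_identical(p$species_epithet, "millefolium")
  expect_identical(p$species_authority, "L.")
  q <- parse_name("achillea millefolium l.")
  expect_identical(q$genus, "Achillea")
  expect_identical(q$species_epithet, "millefolium")
  r <- parse_name("Achillea Millefolium L.",
                  match_options(force_case_insensitive = TRUE))
  expect_true(r$case_insensitive)
  expect_identical(r$species_epithet, "millefolium")
})

test_that("capitalized epithets still parse in case-sensitive mode", {
  p <- parse_name("Achillea Millefolium L.")
  expect_identical(p$species_epithet, "millefolium")
})

test_that("the filius/forma single-letter rules resolve where they can and flag where they cannot", {
  # author before + author-like after: filius, clean
  p <- parse_name("Salix alba L. f. Kern.")
  expect_identical(p$parse_flag, "clean")
  expect_length(p$infra, 0)
  expect_identical(p$species_authority, "L. f. Kern.")
  # bare epithet after, no author before: forma, clean
  q <- parse_name("Achillea millefolium f. alpina")
  expect_identical(q$parse_flag, "clean")
  expect_identical(q$infra[[1]]$rank, "form")
  # author before AND epithet-like after: conflicting signals -> flagged,
  # taken as rank indicator
  r <- parse_name("Salix alba L. f. kern")
  expect_identical(r$parse_flag, "ambiguous_rank_token")
  expect_identical(r$ambiguous_token, "f.")
  expect_identical(r$infra[[1]]$rank, "form")
  expect_identical(r$infra[[1]]$epithet, "kern")
  # trailing filius with nothing after: kept in authority, flagged
  s <- parse_name("Carex alba Willd. f.")
  expect_identical(s$parse_flag, "ambiguous_rank_token")
  expect_length(s$infra, 0)
  expect_match(s$species_authority, "f\\.$")
})

test_that("s. and c. act as rank indicators only when enabled", {
  off <- parse_name("Carex alba s. minor")
  expect_length(off$infra, 0)
  expect_identical(off$species_authority, "s. minor")
  on <- parse_name("Carex alba s. minor",
                   match_options(rank_aliases = list(subspecies = "s")))
  expect_length(on$infra, 1)
  expect_identical(on$infra[[1]]$rank, "subspecies")
  expect_identical(on$infra[[1]]$epithet, "minor")
})

test_that("uppercase filius is still absorbed by the authority when author-like context follows", {
  p <- parse_name("SALIX ALBA L. F. KERN.")
  expect_true(p$case_insensitive)
  expect_length(p$infra, 0)
  expect_match(p$species_authority, "F\\.", ignore.case = TRUE)
})

test_that("up to two infraspecific parts are parsed and extras stay in the authority", {
  p <- parse_name("Poa alpina L. subsp. alpina var. minor Mill.")
  expect_length(p$infra, 2)
  expect_identical(p$infra[[1]]$rank, "subspecies")
  expect_identical(p$infra[[2]]$rank, "variety")
  expect_identical(p$infra[[2]]$authority, "Mill.")
})

test_that("parse errors name the offending input", {
  expect_error(parse_name(""), "empty")
  expect_error(parse_name("   "), "empty")
  expect_error(parse_name("(Opiz) something"), "genus")
})

test_that("recapitalize repairs case and is idempotent", {
  p <- parse_name("Achillea millefolium L.")
  p$genus <- "aCHILLEA"
  p$species_epithet <- "Millefolium"
  r <- recapitalize(p)
  expect_identical(r$genus, "Achillea")
  expect_identical(r$species_epithet, "millefolium")
  expect_identical(recapitalize(r), r)
})

test_that("parsing is deterministic and reassembly is a fixed point", {
  m <- generate_checklist(60, synonym_fraction = 0.2, infra_fraction = 0.3,
                          seed = 99)
  for (nm in m$rows$full_name) {
    norm <- normalize_string(nm)
    p1 <- parse_name(norm)
    p2 <- parse_name(norm)
    expect_identical(p1, p2)
    back <- reassemble_name(p1)
    # reassembly reproduces the normalized string up to capitalization
    expect_identical(tolower(back), tolower(norm))
    # parsing the reassembly is a fixed point
    expect_identical(parse_name(back), parse_name(reassemble_name(parse_name(back))))
  }
})
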