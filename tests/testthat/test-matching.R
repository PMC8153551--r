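th_small <- build_thesaurus(tiny_checklist())

test_that("a one-typo epithet composes the documented component scores", {
  r <- match_name("Achillea milefolius L.", th_small)
  expect_identical(r$status, "unambiguous")
  c1 <- r$candidates[1, ]
  expect_identical(c1$full_name, "Achillea millefolium L.")
  expect_identical(c1$species_ed, 2L)
  expect_equal(c1$returned_score, (mean(c(1, 1 - 2 / 11)) * 0.9 + 1 * 0.1) * 100,
               tolerance = 1e-9)
  expect_equal(c1$returned_score, 91.82, tolerance = 1e-2)
})

test_that("verbatim reference names short-circuit to exact with score 100", {
  for (nm in tiny_checklist()$full_name) {
    r <- match_name(nm, th_small)
    expect_identical(r$status, "exact")
    expect_equal(r$score, 100)
  }
})

test_that("an identical parsed name scores 100 through the component route too", {
  p <- parse_name(normalize_string("Achillea millefolium L."))
  cands <- match_parsed_name(p, th_small)
  expect_equal(cands$returned_score[1], 100)
  expect_identical(cands$full_name[1], "Achillea millefolium L.")
})

test_that("a genus with no stage-1 survivor yields an empty candidate list", {
  p <- parse_name("Xyzqrstu abcus")
  expect_identical(nrow(match_parsed_name(p, th_small)), 0L)
  expect_identical(match_name("Xyzqrstu abcus", th_small)$status, "none")
})

test_that("a matched synonym resolves to its accepted name", {
  r <- match_name("Achillea sudetica Opizz", th_small)  # 1 typo in authority
  expect_identical(r$synonym_name, "Achillea sudetica Opiz")
  expect_identical(r$accepted_name, "Achillea millefolium L.")
})

test_that("the wrong rank indicator costs 0.3 on the infraspecific component", {
  rows <- checklist_rows("Achillea millefolium L. subsp. millefolium")
  th <- build_thesaurus(rows)
  r <- match_name("Achillea millefolium L. var. millefolium", th)
  c1 <- r$candidates[1, ]
  expect_true(c1$infra1_penalty)
  expect_equal(c1$infra1_score, 0.7)
  expect_equal(c1$taxon_score, mean(c(1, 1, 0.7)))
})

test_that("equal-score candidates within the margin are ambiguous, sole survivors are not", {
  rows <- checklist_rows(c("Carex flava L.", "Carex flara L.", "Carex remota L."))
  th <- build_thesaurus(rows)
  amb <- match_name("Carex flasa L.", th)  # one substitution from two entries
  expect_identical(amb$status, "ambiguous")
  expect_gte(nrow(amb$candidates), 2)
  expect_equal(amb$candidates$returned_score[1], amb$candidates$returned_score[2])
  # ties are broken by entry id for reproducibility
  expect_lt(amb$candidates$entry_id[1], amb$candidates$entry_id[2])
  sole <- match_name("Carex remosa L.", th)
  expect_identical(sole$status, "unambiguous")
})

test_that("threshold 100 only lets exact matches through", {
  opts <- match_options(threshold = 100)
  expect_identical(match_name("Achillea milefolius L.", th_small, opts)$status,
                   "none")
  expect_identical(match_name("Achillea millefolium L.", th_small, opts)$status,
                   "exact")
})

test_that("disabling phonetics never adds candidates", {
  m <- generate_checklist(120, synonym_fraction = 0.2, infra_fraction = 0.2,
                          seed = 13)
  th <- build_thesaurus(m$rows)
  on <- match_options(phonetic_enabled = TRUE, threshold = 1)
  off <- match_options(phonetic_enabled = FALSE, threshold = 1)
  set.seed(77)
  picks <- sample(nrow(m$rows), 25)
  for (i in picks) {
    nm <- corrupt_name(m$rows$full_name[i], 1, "substitution", seed = i)$corrupted
    p <- parse_name(normalize_string(nm))
    ids_on <- match_parsed_name(p, th, on)$entry_id
    ids_off <- match_parsed_name(p, th, off)$entry_id
    expect_true(all(ids_off %in% ids_on))
  }
})

test_that("a phonetic hit rescues an epithet beyond the orthographic cap", {
  rows <- checklist_rows("Carex mollifolium L.")
  th <- build_thesaurus(rows)
  # same phonetic key, orthographic distance above the epithet cap
  expect_identical(phonetic_key("malifalim"), phonetic_key("mollifolium"))
  expect_gt(mdld("malifalim", "mollifolium"), 3)
  p <- parse_name("Carex malifalim L.")
  on <- match_parsed_name(p, th, match_options(threshold = 1))
  expect_identical(nrow(on), 1L)
  expect_identical(on$species_via[1], "phonetic")
  off <- match_parsed_name(p, th, match_options(threshold = 1,
                                                phonetic_enabled = FALSE))
  expect_identical(nrow(off), 0L)
})

test_that("the flagged-token verification absorbs filius into the authority when the context matches", {
  rows <- checklist_rows("Salix alba L. f. Kern.")
  th <- build_thesaurus(rows)
  p <- parse_name("Salix alba L. f. kern")
  expect_identical(p$parse_flag, "ambiguous_rank_token")
  cands <- match_parsed_name(p, th, match_options(threshold = 1))
  re <- reparse_authority_check(p, cands, th)
  expect_length(re$infra, 0)
  expect_match(re$species_authority, "f\\.")
  # the full pipeline then scores the name as a straight binomial
  r <- match_name("Salix alba L. f. kern", th)
  expect_identical(r$status, "unambiguous")
  expect_identical(r$accepted_name, "Salix alba L. f. Kern.")
})

test_that("the verification leaves the parse alone when its guards fail", {
  rows <- checklist_rows(c("Salix alba L. f. Kern.",
                           "Salix alba L. f. minor"))
  th <- build_thesaurus(rows)
  # best infraspecific ED is 0: trigger condition not met
  p <- parse_name("Salix alba L. f. minor")
  expect_identical(p$parse_flag, "ambiguous_rank_token")
  cands <- match_parsed_name(p, th, match_options(threshold = 1))
  expect_identical(reparse_authority_check(p, cands, th), p)
  # no candidate authority contains the token: condition (a) fails
  rows2 <- checklist_rows("Salix alba L. subsp. viridis Mill.")
  th2 <- build_thesaurus(rows2)
  p2 <- parse_name("Salix alba L. f. kern")
  cands2 <- match_parsed_name(p2, th2, match_options(threshold = 1))
  expect_identical(reparse_authority_check(p2, cands2, th2), p2)
})
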