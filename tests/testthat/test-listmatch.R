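test_that("text lists are deduplicated in first-occurrence order with the raw total kept", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("Carex alba L.", "Carex nigra L.", "Carex alba L."), path)
  got <- read_name_list(path)
  expect_identical(got$names, c("Carex alba L.", "Carex nigra L."))
  expect_identical(got$total, 3L)
})

test_that("CSV lists read the designated column with the chosen separator", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id;taxon;note", "1;Carex alba L.;x", "2;Carex nigra L.;y"),
             path)
  opts <- match_options(separator = "semicolon", name_column = "taxon")
  got <- read_name_list(path, opts)
  expect_identical(got$names, c("Carex alba L.", "Carex nigra L."))
  expect_error(read_name_list(path, match_options(separator = "semicolon",
                                                  name_column = "species")),
               "not found")
})

test_that("lists over the cap are refused with the limit in the message", {
  path <- tempfile(fileext = ".txt")
  combos <- apply(expand.grid(letters, letters, letters)[1:5001, ], 1,
                  paste, collapse = "")
  writeLines(paste("Aus", combos), path)
  expect_error(read_name_list(path), "5000")
  expect_silent(read_name_list(path, match_options(max_names = 6000)))
})

test_that("a mixed list tallies exact, fuzzy and unmatched names correctly", {
  rows <- tiny_checklist()
  th <- build_thesaurus(rows)
  names <- c("Achillea millefolium L.",     # verbatim -> exact
             "Achillea milefolius L.",      # one typo -> unambiguous
             "Zyxomyrtus qrstus")           # gibberish -> none
  run <- run_list_match(names, th)
  rep <- run$report
  expect_identical(rep$n_exact, 1L)
  expect_identical(rep$n_unambiguous, 1L)
  expect_identical(rep$n_none, 1L)
  expect_identical(rep$n_exact + rep$n_unambiguous + rep$n_ambiguous +
                     rep$n_none, rep$distinct_names)
  expect_error(run_list_match(character(0), th), "empty")
})

test_that("threshold 100 turns every typo into a no-match", {
  th <- build_thesaurus(tiny_checklist())
  names <- c("Achillea milefolius L.", "Calendula oficinalis L.")
  run <- run_list_match(names, th, match_options(threshold = 100))
  expect_identical(run$report$n_none, 2L)
})

test_that("the output CSV has exactly four columns with synonym semantics and report identity", {
  rows <- tiny_checklist()
  th <- build_thesaurus(rows)
  names <- c("Achillea millefolium L.",
             "Achillea sudetica Opiz",      # verbatim synonym -> exact via synonym
             "Achillea milefolius L.",
             "Zyxomyrtus qrstus")
  run <- run_list_match(names, th)
  path <- tempfile(fileext = ".csv")
  write_results_csv(run$results, path)
  csv <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  expect_identical(names(csv),
                   c("original_name", "accepted_name", "synonym", "score"))
  syn_row <- csv[csv$original_name == "Achillea sudetica Opiz", ]
  expect_identical(syn_row$synonym, "Achillea sudetica Opiz")
  expect_identical(syn_row$accepted_name, "Achillea millefolium L.")
  none_row <- csv[csv$original_name == "Zyxomyrtus qrstus", ]
  expect_identical(none_row$accepted_name, "")
  expect_identical(none_row$score, "0")
  # recount the CSV against the report
  n_none <- sum(!nzchar(csv$accepted_name))
  n_amb <- sum(grepl("\\*$", csv$score))
  expect_identical(n_none, run$report$n_none)
  expect_identical(n_amb, run$report$n_ambiguous)
  expect_identical(nrow(csv), run$report$distinct_names)
})

test_that("ambiguous rows carry the top candidate with an asterisked score", {
  th <- build_thesaurus(checklist_rows(c("Carex flava L.", "Carex flara L.")))
  run <- run_list_match("Carex flasa L.", th)
  expect_identical(run$report$n_ambiguous, 1L)
  path <- tempfile(fileext = ".csv")
  write_results_csv(run$results, path)
  csv <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  expect_match(csv$score[1], "\\*$")
  # ties break on entry id, so the first checklist row is the best guess
  expect_identical(csv$accepted_name[1], "Carex flava L.")
})

test_that("matching a list twice writes byte-identical CSVs", {
  m <- generate_checklist(40, synonym_fraction = 0.25, infra_fraction = 0.2,
                          seed = 21)
  th <- build_thesaurus(m$rows)
  names <- synthetic_profile(m, "C", 25, corrupt_fraction = 0.3, seed = 4)
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_results_csv(run_list_match(names, th)$results, p1)
  write_results_csv(run_list_match(names, th)$results, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("accepted names from the output match back as 100% exact", {
  m <- generate_checklist(40, synonym_fraction = 0.25, infra_fraction = 0.2,
                          seed = 22)
  th <- build_thesaurus(m$rows)
  names <- synthetic_profile(m, "C", 20, corrupt_fraction = 0.3, seed = 6)
  run <- run_list_match(names, th)
  accepted <- unique(vapply(run$results, `[[`, "", "accepted_name"))
  accepted <- accepted[nzchar(accepted)]
  expect_gt(length(accepted), 0)
  rerun <- run_list_match(accepted, th)
  expect_identical(rerun$report$n_exact, length(accepted))
})
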