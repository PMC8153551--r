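# nomenmatch

Fuzzy matching of botanical scientific names against a reference
checklist of accepted names and synonyms.

Digitized botanical data — old floras, herbarium labels, vegetation
relevés, image archives — arrive as lists of name strings full of typos,
outdated synonyms, nonstandard infraspecific rank indicators and broken
capitalization. `nomenmatch` aligns any such list to a nomenclatural
backbone and, for interactive search boxes, corrects a free-text query to
the closest substring occurring in the reference names.

## The model

Each input name is **normalized** (special characters, digits,
diacritics, uncertainty tokens), checked for an **exact** hit, **parsed**
into genus / species epithet / authority / up to two infraspecific parts,
and **matched** component-wise against the parsed checklist. A component
matches if it passes an orthographic test (modified Damerau–Levenshtein
distance `mdld()`, which charges a swap of two adjacent blocks of up to
`block_limit` characters only the length of one block) *or* a phonetic
test (equal keys under a Latin-epithet encoder, e.g.
`Huperzia → HIPIRSA`). Components are scored

    ComponentScore = 1 − ED / maxED

with a flat 0.3 penalty on an infraspecific epithet whose rank indicator
is wrong (`var.` typed for a `subsp.`), and aggregated as

    ReturnedScore = (TaxonScore × 0.9 + AuthorScore × 0.1) × 100

where `TaxonScore` is the mean component score and `AuthorScore` a bigram
similarity between authorities. Results are classified exact /
unambiguous / ambiguous / none; synonym hits are resolved to their
accepted names. The query corrector constrains its search to corrections
within ±1 character of the query length that never insert, delete or
replace a blank.

See `vignette source in vignettes/name-matching.Rmd` for the full account
of the models, parameters and design choices.

## Worked example

```r
library(nomenmatch)

rows <- data.frame(
  full_name = c("Achillea millefolium L.",
                "Achillea millefolium L. subsp. sudetica (Opiz) Oborny",
                "Calendula officinalis L.",
                "Achillea sudetica Opiz"),
  status = c("accepted", "accepted", "accepted", "synonym"),
  accepted_ref = c("", "", "", "Achillea millefolium L."))
th <- build_thesaurus(rows)

match_name("Achillea milefolius L.", th)
#> <match_result> 'Achillea milefolius L.': unambiguous -> Achillea millefolium L. [91.82]
```

The misspelled epithet `milefolius` sits at edit distance 2 from
`millefolium` (one insertion, one substitution), so the species component
scores 1 − 2/11 ≈ 0.818, the taxon score averages to 0.909 with the exact
genus, and with the authority in full agreement the returned score is
(0.909 × 0.9 + 1 × 0.1) × 100 ≈ 91.82.

```r
match_name("Achillea sudetica Opiz", th)
#> <match_result> 'Achillea sudetica Opiz': exact -> Achillea millefolium L. (via synonym Achillea sudetica Opiz) [100.00]

nearest_query_match("officialis", th)
#> <query_correction> 'officialis' -> 'officinalis' (1 edit(s), 1 entries)

run <- run_list_match(c("Achillea millefolium L.",
                        "Achillea milefolius L.",
                        "Xyzus abcus"), th)
run$report
#> <list_match_report>
#>   names in the original list: 3
#>   distinct names:             3
#>   exact matches:              1
#>   unambiguous matches:        1
#>   ambiguous matches:          0
#>   no match:                   1
#>   elapsed:                    0.01 s

write_results_csv(run$results, "results.csv")   # four columns:
# original_name, accepted_name, synonym, score
```

A command-line wrapper is installed under `exec/nomenmatch`:

```sh
nomenmatch build --checklist ref.csv --out thesaurus.tsv
nomenmatch match --thesaurus thesaurus.tsv --input names.txt \
    --threshold 70 --rank-alias subsp=s. --out results.csv
nomenmatch query --thesaurus thesaurus.tsv "officialis"
```

Seeded synthetic checklists and corrupted query lists for evaluation come
from `generate_checklist()`, `corrupt_name()` and `synthetic_profile()`.

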