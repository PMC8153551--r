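Package: nomenmatch
Title: Fuzzy Matching of Botanical Scientific Names Against a Checklist
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns lists of botanical scientific names to a reference
    checklist of accepted names and synonyms. Implements a four-stage
    resolver (normalization, exact pre-processing, parsing into
    genus/epithet/authority/infraspecific components, fuzzy matching) built
    on a modified Damerau-Levenshtein distance with adjacent block
    transpositions, a phonetic encoder for Latin epithets, n-gram authority
    similarity, and a component-wise scoring scheme; plus a constrained
    near-match for interactive query strings and a seeded synthetic-data
    generator for closed-loop evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    stringi
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
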