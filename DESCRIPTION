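Package: phonogrow
Title: Growth, Saturation, and Phonetic Distance in Staged Phonological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted phonological networks from proficiency-staged
    lexica (age-of-acquisition stages 1-6), where nodes are phonemic word forms
    and edges link one-segment neighbours weighted by a feature-based phonetic
    similarity score.  Tracks each word's neighbourhood through its growth
    spurts, quantifies proportional degree gain, saturation against a
    first-language density benchmark, and the average phonetic similarity of
    newly acquired neighbours, classifies per-word growth patterns, and fits
    quasi-binomial and zero-inflated negative binomial regressions of the
    growth outcomes on spurt, stage, frequency, and word length.  Includes a
    synthetic staged-lexicon generator with tunable node-aging strength for
    studying obsolescence effects in network growth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    glmmTMB,
    emmeans,
    car,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
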