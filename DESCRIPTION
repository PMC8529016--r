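Package: declentropy
Title: Form-Value Transparency of Italian Noun and Adjective Inflection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds annotated word-form frequency lexica of Italian nouns and
    adjectives, reconstructs inflectional paradigms and declensional classes,
    detects within-POS ambiguous (homograph) forms, and quantifies the
    transparency of the form-value mapping as Shannon entropy (bits) per
    inflectional ending and per declensional class, on both type and token
    counts. Includes a seeded synthetic-lexicon generator with declensional
    class structure, defective paradigms, planted homographs and Zipfian token
    frequencies, so the whole pipeline is testable without corpus data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
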