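Package: hellex
Title: Greek Lexical Database Construction and Psycholinguistic Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building fully annotated Modern Greek psycholinguistic
    lexicons from word-frequency lists. Implements rule-based
    grapheme-to-phoneme transcription, school-grammar orthographic
    syllabification, maximal-onset phonological syllabification driven by
    manner/place-of-articulation and voicing scales, disambiguation of
    ambiguous consonant+i+vowel (CiV) letter patterns, lexical stress
    extraction and ending-based stress prediction, orthographic and
    phonological similarity metrics (Coltheart's N, OLD20/PLD20, rime and
    stress neighbourhood), Zipf-scale word frequencies, syllable frequency
    tables, Fleiss' kappa for annotation agreement, and a seeded generator of
    Greek-like synthetic lexicons with controlled ending-stress consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
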