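# Lexicon table readers/writers (TSV primary, CSV supported), the reversible
# ASCII transliteration dialect, and PoS annotation via dictionary cross-check.

# one-to-one Latin transliteration; tonos marked by a trailing apostrophe on
# the vowel, dialytika by a trailing double quote (tonos mark last: ΐ -> i"')
gk_ascii_letters <- c(
  "α" = "a", "β" = "b", "γ" = "g", "δ" = "d", "ε" = "e", "ζ" = "z",
  "η" = "h", "θ" = "q", "ι" = "i", "κ" = "k", "λ" = "l", "μ" = "m",
  "ν" = "n", "ξ" = "c", "ο" = "o", "π" = "p", "ρ" = "r", "σ" = "s",
  "ς" = "j", "τ" = "t", "υ" = "u", "φ" = "f", "χ" = "x", "ψ" = "y",
  "ω" = "w"
)

#' Reversible ASCII transliteration of Greek words
#'
#' One-to-one Latin mapping of the lowercase Greek alphabet (final sigma
#' distinct), with a trailing apostrophe marking the tonos and a trailing
#' double quote marking dialytika. `ascii_to_greek()` inverts it exactly.
#'
#' @param x Character vector of normalized Greek words.
#' @return Character vector of ASCII-encoded words.
#' @examples
#' greek_to_ascii("γέρος")
#' ascii_to_greek(greek_to_ascii("καΐκι"))
#' @export
greek_to_ascii <- function(x) {
  vapply(x, function(w) {
    ch <- gk_chars(w)
    out <- vapply(ch, function(c1) {
      base <- gk_base_map[[c1]]
      if (c1 == "ς") base <- "ς"
      marks <- paste0(
        if (gk_has_dialytika_char(c1)) "\"" else "",
        if (gk_has_tonos_char(c1)) "'" else ""
      )
      paste0(gk_ascii_letters[[base]], marks)
    }, character(1))
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname greek_to_ascii
#' @export
ascii_to_greek <- function(x) {
  rev_map <- stats::setNames(names(gk_ascii_letters), gk_ascii_letters)
  vapply(x, function(w) {
    ch <- gk_chars(w)
    out <- character(0)
    for (c1 in ch) {
      if (c1 == "'") {
        last <- out[length(out)]
        out[length(out)] <- if (gk_has_dialytika_char(last)) {
          c("ι" = "ΐ", "ϊ" = "ΐ", "ϋ" = "ΰ")[[last]]
        } else {
          gk_tonos_map[[last]]
        }
      } else if (c1 == "\"") {
        out[length(out)] <- c("ι" = "ϊ", "υ" = "ϋ")[[out[length(out)]]]
      } else {
        out <- c(out, rev_map[[c1]])
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a lexicon table
#'
#' Reads a delimited lexicon file (TSV by default, CSV by extension) with at
#' minimum a `word` column and a `freq_count` token frequency column. Malformed
#' rows (unparseable word, missing or negative frequency) are not silently
#' dropped: they are collected into the `"problems"` attribute and reported
#' with a warning.
#'
#' @param path File path.
#' @param dialect `"utf8"` (Greek text) or `"ascii"` (the [greek_to_ascii()]
#'   transliteration, decoded on read).
#' @return A tibble with normalized `word` and integer `freq_count` columns
#'   plus any further columns in the file; attribute `"problems"` holds the
#'   rejected rows with a `reason` column.
#' @seealso [write_lexicon()]
#' @export
read_lexicon <- function(path, dialect = c("utf8", "ascii")) {
  dialect <- match.arg(dialect)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  raw <- reader(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("word", "freq_count") %in% names(raw))) {
    stop(
      "schema error: lexicon file must have columns `word` and `freq_count`",
      call. = FALSE
    )
  }
  if (dialect == "ascii") raw$word <- ascii_to_greek(raw$word)
  ok_word <- vapply(raw$word, function(w) {
    !inherits(try(normalize_greek(w), silent = TRUE), "try-error")
  }, logical(1))
  freq <- suppressWarnings(as.numeric(raw$freq_count))
  ok_freq <- !is.na(freq) & freq >= 0
  bad <- !ok_word | !ok_freq
  problems <- raw[bad, , drop = FALSE]
  if (nrow(problems) > 0) {
    problems$reason <- ifelse(!ok_word[bad], "malformed word", "bad frequency")
    warning(nrow(problems), " malformed row(s) rejected; see attr(, \"problems\")",
      call. = FALSE
    )
  }
  out <- raw[!bad, , drop = FALSE]
  out$word <- normalize_greek(out$word)
  out$freq_count <- as.numeric(out$freq_count)
  attr(out, "problems") <- problems
  out
}

#' Write a lexicon table
#'
#' TSV is the primary on-disk format; CSV export is chosen by the `.csv`
#' extension. The ASCII dialect transliterates the `word` column (and gold/
#' syllable columns are left as-is).
#'
#' @param x A lexicon tibble.
#' @param path Output path (`.tsv` or `.csv`).
#' @param dialect `"utf8"` or `"ascii"`.
#' @return `x`, invisibly.
#' @export
write_lexicon <- function(x, path, dialect = c("utf8", "ascii")) {
  dialect <- match.arg(dialect)
  if (dialect == "ascii") x$word <- greek_to_ascii(x$word)
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv
  } else {
    readr::write_tsv
  }
  writer(x, path, progress = FALSE)
  invisible(x)
}

#' Annotate a lexicon with part-of-speech tags
#'
#' Cross-checks every entry against a dictionary mapping words to an ordered
#' list of PoS categories. The dictionary's first category becomes the primary
#' tag; the remaining categories become secondary tags. Unmatched words are
#' tagged `"unknown"` (a value, not an error) and counted in a message.
#'
#' @param lexicon A data frame with a `word` column.
#' @param dictionary A data frame with columns `word` and `pos`; `pos` is a
#'   comma-separated list of categories, primary first (e.g.
#'   `"adverb,adjective"`).
#' @return The lexicon with `pos_primary` and `pos_secondary` columns added.
#' @export
pos_annotate <- function(lexicon, dictionary) {
  stopifnot("word" %in% names(lexicon), all(c("word", "pos") %in% names(dictionary)))
  key <- strip_stress(lexicon$word)
  dkey <- strip_stress(dictionary$word)
  hit <- match(key, dkey)
  tags <- stringr::str_split(dictionary$pos[hit], ",\\s*")
  lexicon$pos_primary <- vapply(tags, function(t) {
    if (length(t) == 0 || all(is.na(t))) "unknown" else t[1]
  }, character(1))
  lexicon$pos_secondary <- vapply(tags, function(t) {
    if (length(t) <= 1 || all(is.na(t))) "" else paste(t[-1], collapse = ",")
  }, character(1))
  n_unknown <- sum(lexicon$pos_primary == "unknown")
  if (n_unknown > 0) {
    message(n_unknown, " entr(ies) not found in the PoS dictionary; tagged unknown")
  }
  lexicon
}
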