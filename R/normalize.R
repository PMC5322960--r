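#' Normalize raw text to canonical lowercase Greek
#'
#' Canonicalises input for all downstream rules: Unicode composition (NFC), so
#' accented vowels are single code points; whitespace trimming; optional
#' lowercasing (stress diacritics are not marked in uppercase Greek, so
#' uppercase input is accepted but lowercased with a warning). Words containing
#' characters outside the lowercase Greek letter inventory are rejected.
#'
#' @param x Character vector of raw words.
#' @param lowercase Lowercase uppercase input (default `TRUE`). With
#'   `lowercase = FALSE`, uppercase letters are still rejected as non-canonical.
#' @return Character vector of normalized words.
#' @examples
#' normalize_greek("  ΓΈΡΟΣ ")
#' normalize_greek("γέρος")
#' @seealso [strip_stress()], [stressed_vowel_index()]
#' @export
normalize_greek <- function(x, lowercase = TRUE) {
  stopifnot(is.character(x))
  out <- stringi::stri_trans_nfc(stringr::str_trim(x))
  if (any(!nzchar(out) | is.na(out))) {
    stop("empty word after whitespace stripping", call. = FALSE)
  }
  has_upper <- stringr::str_detect(out, "\\p{Lu}")
  if (any(has_upper)) {
    if (!lowercase) {
      stop("uppercase input with lowercase = FALSE: ", out[has_upper][1], call. = FALSE)
    }
    warning(
      sum(has_upper), " uppercase word(s) lowercased during normalization",
      call. = FALSE
    )
    out[has_upper] <- stringi::stri_trans_tolower(out[has_upper], locale = "el")
  }
  bad <- stringr::str_remove_all(out, paste0("[", paste(gk_all_letters, collapse = ""), "]"))
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop(
      "non-Greek character \"", stringr::str_sub(bad[i], 1, 1),
      "\" in word \"", out[i], "\"",
      call. = FALSE
    )
  }
  out
}

#' Remove the stress diacritic (tonos)
#'
#' Replaces the tonos-bearing vowel with its unaccented counterpart; dialytika
#' is retained. Idempotent and length-preserving on composed strings.
#'
#' @param x Character vector of normalized words.
#' @return Character vector with stress diacritics removed.
#' @examples
#' strip_stress("γέρος")
#' strip_stress("καμβάς")
#' @export
strip_stress <- function(x) {
  chartr(
    paste(names(gk_detonos_map), collapse = ""),
    paste(unname(gk_detonos_map), collapse = ""),
    x
  )
}

#' Index of the stressed vowel letter
#'
#' Position (1-based) of the vowel letter bearing the tonos, or `NA` for
#' unstressed words (monosyllables may legitimately lack a tonos). A word with
#' more than one tonos is malformed and raises an error.
#'
#' @param x Character vector of normalized words.
#' @return Integer vector of letter indices (`NA` where unstressed).
#' @examples
#' stressed_vowel_index("γέρος")
#' stressed_vowel_index("γερος")
#' @export
stressed_vowel_index <- function(x) {
  vapply(x, function(w) {
    ch <- gk_chars(w)
    idx <- which(vapply(ch, gk_has_tonos_char, logical(1)))
    if (length(idx) > 1) {
      stop("malformed word \"", w, "\": more than one tonos", call. = FALSE)
    }
    if (length(idx) == 0) NA_integer_ else as.integer(idx)
  }, integer(1), USE.NAMES = FALSE)
}

# TRUE if the word carries a tonos anywhere
gk_is_stressed <- function(x) {
  stringr::str_detect(x, paste0(
    "[", paste(c(gk_tonos_vowels, gk_dialytika_tonos_vowels), collapse = ""), "]"
  ))
}
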