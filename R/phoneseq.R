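# Phone sequences: ordered phone symbols from a fixed Modern Greek inventory
# plus at most one stress marker sitting on a vowel phone. Symbols follow the
# "paper style" common in Greek psycholinguistic resources (δ, γ, θ, ε for the
# voiced dental/velar fricatives, the dental voiceless fricative and the mid
# front vowel); as_ipa() maps to standard IPA (ð, ɣ, θ, e).

gk_vowel_phones <- c("a", "ε", "i", "o", "u")

gk_consonant_phones <- c(
  "p", "b", "t", "d", "k", "g", "c",
  "f", "v", "θ", "δ", "s", "z", "x", "γ", "ç", "ʝ",
  "m", "n", "ɲ", "ŋ", "ɱ",
  "l", "r", "ʎ",
  "ts", "dz"
)

gk_phone_inventory <- c(gk_vowel_phones, gk_consonant_phones)

#' Construct a phone sequence
#'
#' @param phones Character vector of phone symbols from the package inventory
#'   (see [phone_inventory()]).
#' @param stress Index of the stressed vowel phone, or `NA` for unstressed
#'   sequences.
#' @return An object of class `gk_phoneseq`.
#' @examples
#' phone_seq(c("ɲ", "o", "θ", "o"), stress = 2)
#' @export
phone_seq <- function(phones, stress = NA_integer_) {
  stopifnot(is.character(phones), length(phones) >= 1)
  bad <- setdiff(phones, gk_phone_inventory)
  if (length(bad) > 0) {
    stop("phone(s) outside the inventory: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stress <- as.integer(stress)
  if (!is.na(stress)) {
    stopifnot(stress >= 1, stress <= length(phones))
    if (!phones[stress] %in% gk_vowel_phones) {
      stop("stress marker must sit on a vowel phone", call. = FALSE)
    }
  }
  structure(list(phones = phones, stress = stress), class = "gk_phoneseq")
}

#' Phone inventory
#'
#' @return A tibble with columns `phone` and `class` (`"vowel"`/`"consonant"`).
#' @export
phone_inventory <- function() {
  tibble::tibble(
    phone = gk_phone_inventory,
    class = rep(c("vowel", "consonant"), c(length(gk_vowel_phones), length(gk_consonant_phones)))
  )
}

#' @export
format.gk_phoneseq <- function(x, ...) {
  ph <- x$phones
  if (!is.na(x$stress)) ph <- append(ph, "'", after = x$stress - 1L)
  paste(ph, collapse = "")
}

#' @export
print.gk_phoneseq <- function(x, ...) {
  cat("<phoneseq> [", format(x), "]\n", sep = "")
  invisible(x)
}

#' @export
as.character.gk_phoneseq <- function(x, ...) format(x)

#' Convert paper-style phone symbols to standard IPA
#'
#' @param x A `gk_phoneseq` or character vector of phone symbols.
#' @return Same shape as the input, with δ, γ, ε mapped to ð, ɣ, e.
#' @export
as_ipa <- function(x) {
  map <- c("δ" = "ð", "γ" = "ɣ", "ε" = "e") # δ γ ε
  conv <- function(p) ifelse(p %in% names(map), map[p], p)
  if (inherits(x, "gk_phoneseq")) {
    x$phones <- unname(conv(x$phones))
    return(x)
  }
  unname(conv(x))
}

gk_is_vowel_phone <- function(p) p %in% gk_vowel_phones

gk_n_vowel_phones <- function(x) sum(gk_is_vowel_phone(x$phones))
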