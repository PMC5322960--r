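# Letter inventories and diacritic maps for lowercase monotonic Greek.
# All strings in this package are kept in composed (NFC) form so that an
# accented vowel is a single code point and letter indices match letter counts.

gk_plain_vowels <- c("α", "ε", "η", "ι", "ο", "υ", "ω") # α ε η ι ο υ ω

# tonos-bearing vowels, aligned with gk_plain_vowels; ΐ ΰ carry dialytika too
gk_tonos_vowels <- c("ά", "έ", "ή", "ί", "ό", "ύ", "ώ")
gk_dialytika_vowels <- c("ϊ", "ϋ") # ϊ ϋ
gk_dialytika_tonos_vowels <- c("ΐ", "ΰ") # ΐ ΰ

gk_consonant_letters <- c(
  "β", "γ", "δ", "ζ", "θ", "κ", "λ", "μ",
  "ν", "ξ", "π", "ρ", "σ", "ς", "τ", "φ",
  "χ", "ψ"
) # β γ δ ζ θ κ λ μ ν ξ π ρ σ ς τ φ χ ψ

gk_all_vowel_letters <- c(
  gk_plain_vowels, gk_tonos_vowels, gk_dialytika_vowels, gk_dialytika_tonos_vowels
)

gk_all_letters <- c(gk_all_vowel_letters, gk_consonant_letters)

# map any letter to its plain (diacritic-free) base; final sigma maps to sigma
gk_base_map <- stats::setNames(
  c(
    gk_plain_vowels,
    gk_plain_vowels, # tonos
    c("ι", "υ"), # dialytika
    c("ι", "υ"), # dialytika + tonos
    gk_consonant_letters
  ),
  c(
    gk_plain_vowels, gk_tonos_vowels, gk_dialytika_vowels,
    gk_dialytika_tonos_vowels, gk_consonant_letters
  )
)
gk_base_map[["ς"]] <- "σ" # ς -> σ

# tonos removal preserves dialytika: ΐ -> ϊ, ΰ -> ϋ
gk_detonos_map <- stats::setNames(
  c(gk_plain_vowels, c("ϊ", "ϋ")),
  c(gk_tonos_vowels, gk_dialytika_tonos_vowels)
)

# tonos addition (used by the synthetic generator)
gk_tonos_map <- stats::setNames(gk_tonos_vowels, gk_plain_vowels)

# two-letter vowel graphemes; αυ/ευ/ηυ pattern with a consonantal second element
gk_vowel_digraphs <- c(
  "αι", "ει", "οι", "υι", "ου"
) # αι ει οι υι ου
gk_semivowel_digraphs <- c("αυ", "ευ", "ηυ") # αυ ευ ηυ

gk_consonant_digraphs <- c(
  "μπ", "ντ", "γκ", "γγ",
  "τσ", "τζ"
) # μπ ντ γκ γγ τσ τζ

# vowel-letter groups whose isolated value is [i]: ι η υ, ει οι υι
gk_i_sound_groups <- c(
  "ι", "η", "υ",
  "ει", "οι", "υι"
)

gk_chars <- function(x) stringr::str_split(x, "")[[1]]

gk_is_vowel_letter <- function(ch) ch %in% gk_all_vowel_letters
gk_is_consonant_letter <- function(ch) ch %in% gk_consonant_letters

gk_has_tonos_char <- function(ch) {
  ch %in% c(gk_tonos_vowels, gk_dialytika_tonos_vowels)
}

gk_has_dialytika_char <- function(ch) {
  ch %in% c(gk_dialytika_vowels, gk_dialytika_tonos_vowels)
}

gk_base_letters <- function(x) {
  chartr(
    paste(names(gk_base_map), collapse = ""),
    paste(unname(gk_base_map), collapse = ""),
    x
  )
}

#' Greek letter classification
#'
#' The lowercase Modern Greek letter inventory used throughout the package:
#' the 24-letter alphabet plus the word-final sigma allograph, each letter
#' classified as vowel or consonant, together with the two-letter vowel and
#' consonant graphemes (digraphs) the transcription and syllabification rules
#' recognise.
#'
#' @return A tibble with columns `letter`, `category` (`"vowel"` or
#'   `"consonant"`) and `digraph` (logical; `TRUE` rows are two-letter
#'   graphemes rather than alphabet letters).
#' @examples
#' greek_letter_classes()
#' @export
greek_letter_classes <- function() {
  dplyr::bind_rows(
    tibble::tibble(letter = gk_plain_vowels, category = "vowel", digraph = FALSE),
    tibble::tibble(letter = gk_consonant_letters, category = "consonant", digraph = FALSE),
    tibble::tibble(
      letter = c(gk_vowel_digraphs, gk_semivowel_digraphs),
      category = "vowel", digraph = TRUE
    ),
    tibble::tibble(letter = gk_consonant_digraphs, category = "consonant", digraph = TRUE)
  )
}
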