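# Rule-based grapheme-to-phoneme transcription of Modern Greek. Greek
# orthography is highly consistent in the print-to-sound direction; the whole
# mapping lives in this file as one ordered set of context rules so that
# disagreements are auditable:
#
#   1. tokenization, longest grapheme first (vowel digraphs αι ει οι υι ου,
#      semivowel digraphs αυ ευ ηυ, consonant digraphs μπ ντ γκ γγ τσ τζ)
#   2. CiV sites merged into glide groups per the supplied parse decisions
#   3. vowel groups:   α→a  ε/αι→ε  η/ι/υ/ει/οι/υι→i  ο/ω→o  ου→u;
#      αυ/ευ/ηυ → a/ε/i + [v] before vowels and voiced consonants, [f]
#      before voiceless consonants and word-finally
#   4. consonant digraphs: word-initial μπ/ντ/γκ → b/d/g; word-medial →
#      mb/nd/ŋg (simplified to b/d/g unless keep_nasals); γγ → ŋg; τσ→ts τζ→dz
#   5. velar palatalization before front vowels [ε i]: κ→c, γ→ʝ, χ→ç
#   6. σ/ς → z before a voiced consonant, else s
#   7. glide groups: preceding n→ɲ, l→ʎ, κ→c, γ→ʝ, χ→ç (glide absorbed);
#      m → m+ɲ; other voiceless obstruents → +ç; voiced obstruents and r → +ʝ
#
# The stress marker lands on the vowel phone of the tonos-bearing vowel group.

gk_front_vowel_phones <- c("ε", "i")

gk_voiced_phones <- c(
  "v", "δ", "γ", "z", "b", "d", "g", "ʝ",
  "m", "n", "ɲ", "ŋ", "ɱ", "l", "r", "ʎ", "dz"
)

gk_voiceless_obstruents <- c("p", "t", "k", "c", "f", "θ", "s", "x", "ç", "ts")
gk_voiced_obstruents <- c("b", "d", "g", "v", "δ", "z", "dz")

# single-letter consonant map for letters without context rules
gk_simple_consonant_map <- c(
  "β" = "v", "δ" = "δ", "ζ" = "z", "θ" = "θ", "λ" = "l", "μ" = "m",
  "ν" = "n", "π" = "p", "ρ" = "r", "τ" = "t", "φ" = "f"
)

# First phone the j-th token will produce, used for lookahead (σ voicing,
# velar palatalization, αυ/ευ realization). For glide groups the nucleus
# decides.
gk_lead_phone <- function(toks, j) {
  if (j > length(toks$token)) {
    return(NA_character_)
  }
  if (toks$type[j] == "vowel") {
    nucleus <- if (toks$glide[j]) toks$nucleus[j] else toks$token[j]
    return(gk_vowel_group_phones(nucleus)$phones[1])
  }
  base <- gk_base_letters(toks$token[j])
  switch(base,
    "μπ" = "b", "ντ" = "d", "γκ" = "g", "γγ" = "g", "τσ" = "ts", "τζ" = "dz",
    "γ" = "γ", "κ" = "k", "χ" = "x", "σ" = "s", "ξ" = "k", "ψ" = "p",
    unname(gk_simple_consonant_map[base])
  )
}

# phones of a vowel group that is not a semivowel digraph; the αυ/ευ consonant
# element is resolved by the caller (needs lookahead)
gk_vowel_group_phones <- function(token) {
  base <- gk_base_letters(strip_stress(token))
  vowel_map <- c(
    "α" = "a", "ε" = "ε", "η" = "i", "ι" = "i", "υ" = "i", "ο" = "o", "ω" = "o",
    "αι" = "ε", "ει" = "i", "οι" = "i", "υι" = "i", "ου" = "u",
    "αυ" = "a", "ευ" = "ε", "ηυ" = "i"
  )
  phone <- unname(vowel_map[base])
  if (is.na(phone)) stop("unmappable vowel group: ", token, call. = FALSE)
  list(phones = phone, semivowel = base %in% gk_semivowel_digraphs)
}

#' Grapheme-to-phoneme transcription of one word
#'
#' Deterministically transcribes a normalized Greek word into a [phone_seq()],
#' applying the ordered context rules documented in this file. Ambiguous CiV
#' sites are realized per the supplied parse: when the two vowel graphemes are
#' parsed apart the medial i is a full vowel; when parsed together the i is
#' absorbed and the preceding consonant is palatalised ([n]→[ɲ], [l]→[ʎ],
#' velars → palatals) or followed by [ç]/[ʝ].
#'
#' @param word A normalized Greek word (single string).
#' @param civ A [civ_policy()], or a character vector of per-site decisions
#'   (`"one"`/`"two"`) in site order. Ignored for words without CiV sites.
#' @param keep_nasals Keep the nasal in word-medial [mb]/[nd]/[ŋg] (allophonic
#'   forms); by default [simplify_nasals()] is applied so the output never
#'   contains a nasal + homorganic voiced stop.
#' @return A `gk_phoneseq`.
#' @examples
#' g2p("νιώθω")
#' g2p("αντένα")
#' g2p("κυάνιο")
#' @seealso [transcribe()] for the vectorized, tabular interface.
#' @export
g2p <- function(word, civ = default_civ_policy(), keep_nasals = FALSE) {
  stopifnot(is.character(word), length(word) == 1)
  decisions <- gk_civ_decisions(word, civ)
  toks <- gk_tokenize(word, consonant_digraphs = TRUE)
  toks <- gk_apply_civ(toks, decisions)
  n <- length(toks$token)

  phones <- character(0)
  stress <- NA_integer_
  word_vowel_seen <- FALSE

  for (j in seq_len(n)) {
    lead <- gk_lead_phone(toks, j + 1L)

    if (toks$type[j] == "vowel") {
      if (toks$glide[j]) {
        # realize the absorbed i: transform or augment the preceding consonant
        prev <- if (length(phones) > 0) phones[length(phones)] else NA_character_
        if (is.na(prev) || gk_is_vowel_phone(prev)) {
          # defensive: a bare i+V with no onset consonant reads as [ʝ]
          phones <- c(phones, "ʝ")
        } else if (prev == "n") {
          phones[length(phones)] <- "ɲ"
        } else if (prev == "l") {
          phones[length(phones)] <- "ʎ"
        } else if (prev == "k") {
          phones[length(phones)] <- "c"
        } else if (prev == "γ") {
          phones[length(phones)] <- "ʝ"
        } else if (prev == "x") {
          phones[length(phones)] <- "ç"
        } else if (prev == "m") {
          phones <- c(phones, "ɲ")
        } else if (prev %in% gk_voiceless_obstruents) {
          phones <- c(phones, "ç")
        } else {
          phones <- c(phones, "ʝ") # voiced obstruents and r
        }
        vg <- gk_vowel_group_phones(toks$nucleus[j])
      } else {
        vg <- gk_vowel_group_phones(toks$token[j])
      }
      phones <- c(phones, vg$phones)
      if (toks$accented[j]) stress <- length(phones)
      word_vowel_seen <- TRUE
      if (vg$semivowel) {
        voiced_next <- !is.na(lead) &&
          (gk_is_vowel_phone(lead) || lead %in% gk_voiced_phones)
        phones <- c(phones, if (voiced_next) "v" else "f")
      }
    } else {
      base <- gk_base_letters(toks$token[j])
      initial <- j == 1L
      front <- !is.na(lead) && lead %in% gk_front_vowel_phones
      add <- switch(base,
        "μπ" = if (initial) "b" else c("m", "b"),
        "ντ" = if (initial) "d" else c("n", "d"),
        "γκ" = if (initial) "g" else c("ŋ", "g"),
        "γγ" = c("ŋ", "g"),
        "τσ" = "ts",
        "τζ" = "dz",
        "γ" = if (front) "ʝ" else "γ",
        "κ" = if (front) "c" else "k",
        "χ" = if (front) "ç" else "x",
        "σ" = if (!is.na(lead) && lead %in% gk_voiced_phones) "z" else "s",
        "ξ" = c("k", "s"),
        "ψ" = c("p", "s"),
        {
          p <- gk_simple_consonant_map[base]
          if (is.na(p)) {
            stop(
              "unmappable grapheme \"", toks$token[j], "\" at position ",
              toks$start[j], " in word \"", word, "\"",
              call. = FALSE
            )
          }
          unname(p)
        }
      )
      phones <- c(phones, add)
    }
  }

  if (!word_vowel_seen) {
    stop("word \"", word, "\" has no vowel nucleus", call. = FALSE)
  }
  # degemination: Greek has no phonetic geminates (σσ, λλ, κκ ... -> one phone)
  if (length(phones) > 1) {
    dup <- c(FALSE, phones[-1] == phones[-length(phones)] &
      !phones[-1] %in% gk_vowel_phones)
    if (any(dup)) {
      if (!is.na(stress)) stress <- stress - sum(dup[seq_len(stress)])
      phones <- phones[!dup]
    }
  }
  out <- phone_seq(phones, stress)
  if (!keep_nasals) out <- simplify_nasals(out)
  out
}

#' Drop nasals before homorganic voiced stops
#'
#' Every nasal + homorganic voiced stop pair ([mb], [nd], [ŋg]) loses the
#' nasal; the labiodental nasal [ɱ] is first mapped to [m]. Idempotent.
#'
#' @param x A `gk_phoneseq`.
#' @return A `gk_phoneseq`.
#' @examples
#' simplify_nasals(phone_seq(c("a", "k", "u", "m", "b", "a", "o"), stress = 6))
#' @export
simplify_nasals <- function(x) {
  stopifnot(inherits(x, "gk_phoneseq"))
  ph <- x$phones
  ph[ph == "ɱ"] <- "m"
  homorganic <- c("m" = "b", "n" = "d", "ŋ" = "g")
  drop <- rep(FALSE, length(ph))
  for (i in seq_len(length(ph) - 1)) {
    if (ph[i] %in% names(homorganic) && ph[i + 1] == homorganic[[ph[i]]]) {
      drop[i] <- TRUE
    }
  }
  stress <- x$stress
  if (!is.na(stress)) stress <- stress - sum(drop[seq_len(stress)])
  phone_seq(ph[!drop], stress)
}

#' Normalize a transcription for cross-database comparison
#'
#' The three adjustments applied before comparing transcriptions across
#' lexical databases: (i) monosyllables lose their (redundant) stress marker;
#' (ii) nasal + homorganic stop simplification; (iii) the labiodental nasal is
#' treated as [m]. Idempotent.
#'
#' @param x A `gk_phoneseq`.
#' @param monosyllable Logical; defaults to whether the sequence has exactly
#'   one vowel phone.
#' @return A `gk_phoneseq`.
#' @export
comparison_normalize <- function(x, monosyllable = NULL) {
  stopifnot(inherits(x, "gk_phoneseq"))
  out <- simplify_nasals(x)
  if (is.null(monosyllable)) monosyllable <- gk_n_vowel_phones(out) == 1L
  if (monosyllable) out$stress <- NA_integer_
  out
}

#' Transcribe a vector of words
#'
#' Vectorized, tabular interface over [g2p()]: one row per word with the
#' formatted transcription (apostrophe before the stressed vowel), the phone
#' vector, and the stress index.
#'
#' @inheritParams g2p
#' @param x Character vector of normalized Greek words.
#' @param style `"paper"` (δ, γ, ε symbols) or `"ipa"` (ð, ɣ, e).
#' @return A tibble with columns `word`, `transcription`, `phones` (list of
#'   character vectors), `stress`.
#' @examples
#' transcribe(c("γυάλα", "αντένα"))
#' @export
transcribe <- function(x, civ = default_civ_policy(), keep_nasals = FALSE,
                       style = c("paper", "ipa")) {
  style <- match.arg(style)
  seqs <- purrr::map(x, g2p, civ = civ, keep_nasals = keep_nasals)
  if (style == "ipa") seqs <- purrr::map(seqs, as_ipa)
  tibble::tibble(
    word = x,
    transcription = purrr::map_chr(seqs, format),
    phones = purrr::map(seqs, "phones"),
    stress = purrr::map_int(seqs, "stress")
  )
}
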