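# Grapheme tokenizer shared by the orthographic syllabifier and the
# grapheme-to-phoneme rules. A token is either a vowel group (single vowel
# letter or a two-letter vowel grapheme) or a consonant grapheme (single letter
# or, when `consonant_digraphs = TRUE`, one of the two-letter consonant
# graphemes recognised by the transcription rules).
#
# Vowel digraphs are read greedily left to right. A two-letter vowel grapheme
# is only formed when the first letter is unaccented and neither letter carries
# dialytika (dialytika marks the hiatus reading, a tonos on the first vowel
# splits the pair).
#
# Tokens are kept as a plain list of parallel vectors: this code sits on the
# per-word hot path of the whole pipeline.

gk_tokenize <- function(word, consonant_digraphs = FALSE) {
  ch <- gk_chars(word)
  n <- length(ch)
  token <- character(n)
  type <- character(n)
  start <- integer(n)
  m <- 0L
  i <- 1L
  while (i <= n) {
    c1 <- ch[i]
    m <- m + 1L
    start[m] <- i
    if (gk_is_vowel_letter(c1)) {
      type[m] <- "vowel"
      take <- 1L
      if (i < n && gk_is_vowel_letter(ch[i + 1])) {
        c2 <- ch[i + 1]
        pair <- paste0(gk_base_map[[c1]], gk_base_map[[c2]])
        if (pair %in% c(gk_vowel_digraphs, gk_semivowel_digraphs) &&
          !gk_has_tonos_char(c1) &&
          !gk_has_dialytika_char(c1) && !gk_has_dialytika_char(c2)) {
          take <- 2L
        }
      }
    } else {
      type[m] <- "consonant"
      take <- 1L
      if (consonant_digraphs && i < n &&
        paste0(c1, ch[i + 1]) %in% gk_consonant_digraphs) {
        take <- 2L
      }
    }
    token[m] <- if (take == 1L) c1 else paste0(c1, ch[i + 1])
    i <- i + take
  }
  token <- token[seq_len(m)]
  type <- type[seq_len(m)]
  start <- start[seq_len(m)]
  accented <- stringr::str_detect(token, gk_tonos_class_re)
  dialytika <- stringr::str_detect(token, gk_dialytika_class_re)
  list(
    token = token, type = type, start = start,
    accented = accented, dialytika = dialytika,
    i_sound = type == "vowel" & !accented & !dialytika &
      gk_base_letters(token) %in% gk_i_sound_groups,
    glide = logical(m),
    nucleus = ifelse(type == "vowel", token, NA_character_)
  )
}

gk_tonos_class_re <- paste0(
  "[", paste(c(gk_tonos_vowels, gk_dialytika_tonos_vowels), collapse = ""), "]"
)
gk_dialytika_class_re <- paste0(
  "[", paste(c(gk_dialytika_vowels, gk_dialytika_tonos_vowels), collapse = ""), "]"
)

#' Locate ambiguous CiV letter patterns
#'
#' A CiV site is a consonant followed by an unaccented i-sounding vowel group
#' (ι, η, υ, ει, οι, υι without dialytika) followed by another vowel group. The
#' orthography alone cannot determine whether the middle element is a full
#' vowel (two syllables, as in κυάνιο) or a glide / palatalisation trigger (one
#' syllable, as in γυάλα); see [civ_policy()] for how sites are resolved.
#'
#' @param word A normalized Greek word (single string).
#' @return A tibble with one row per site: `site` (ordinal within the word),
#'   `start` (letter index of the i-group), `cluster` (the stress-stripped
#'   vowel-letter pattern, e.g. `"ιο"`).
#' @examples
#' civ_sites("κυάνιο")
#' civ_sites("γέρος")
#' @export
civ_sites <- function(word) {
  stopifnot(is.character(word), length(word) == 1)
  s <- gk_civ_sites_tokens(gk_tokenize(word))
  tibble::tibble(site = s$site, start = s$start, cluster = s$cluster)
}

# internal: list(site, start, cluster) vectors
gk_civ_sites_tokens <- function(toks) {
  n <- length(toks$token)
  hit <- which(
    toks$i_sound &
      seq_len(n) > 1L & seq_len(n) < n &
      c("", toks$type[-n]) == "consonant" &
      c(toks$type[-1], "") == "vowel"
  )
  list(
    site = seq_along(hit),
    start = toks$start[hit],
    cluster = strip_stress(paste0(toks$token[hit], toks$token[hit + 1L]))
  )
}

# Merge one-syllable CiV sites into glide vowel groups. `decisions` is a
# character vector ("one"/"two") aligned with gk_civ_sites_tokens(toks).
# Merging proceeds right to left so earlier token indices stay valid.
gk_apply_civ <- function(toks, decisions) {
  sites <- gk_civ_sites_tokens(toks)
  if (length(sites$site) == 0L) {
    return(toks)
  }
  stopifnot(length(decisions) == length(sites$site), all(decisions %in% c("one", "two")))
  for (s in rev(seq_along(sites$site))) {
    if (decisions[s] != "one") next
    j <- which(toks$start == sites$start[s] & toks$type == "vowel")
    toks$token[j + 1L] <- paste0(toks$token[j], toks$token[j + 1L])
    toks$start[j + 1L] <- toks$start[j]
    toks$glide[j + 1L] <- TRUE
    for (f in names(toks)) toks[[f]] <- toks[[f]][-j]
  }
  toks
}
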