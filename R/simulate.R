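# Seeded generator of Greek-like lexicons with controlled statistical
# structure. Words are composed from attested syllable parts (onsets legal
# under both syllabifiers, open syllables word-internally, an optional ς/ν
# word-final coda), so gold syllabifications and transcriptions exist by
# construction and the parsers can be tested against them. The ending -> stress
# association is planted directly: every polysyllable draws an ending from a
# finite inventory and receives its ending's modal stress position with
# probability theta, otherwise one of the other positions licensed by its
# length, uniformly. Token counts follow a rank-frequency power law.
#
# Defaults emulate the distributional structure reported for the Greek
# lexicon: the syllable-length distribution of lemma types, the PoS mixture
# (nouns 58.5%, adjectives 25.8%, verbs 14.2%, adverbs 1.5%), pre-final
# dominance for disyllables shifting to antepenultimate dominance for lengths
# >= 4, and adjectives disfavouring the pre-final position.

# onset letter clusters legal under the strict phonological rules and attested
# word-initially, so both syllabifiers recover the generative parse
sim_onsets <- function() {
  singles <- c(
    "β", "γ", "δ", "ζ", "θ", "κ", "λ", "μ", "ν",
    "ξ", "π", "ρ", "σ", "τ", "φ", "χ", "ψ"
  )
  clusters <- c(
    "θρ", "τρ", "πρ", "κρ", "βρ", "δρ", "γρ", "φρ", "χρ",
    "πλ", "κλ", "βλ", "γλ", "φλ", "χλ", "θλ",
    "πν", "κν", "θν", "γν", "μν", "τμ",
    "κτ", "φτ", "φθ", "γδ"
  )
  c(singles, clusters)
}

sim_nuclei <- function() {
  c(
    "α", "ε", "η", "ι", "ο", "υ", "ω",
    "ου", "αι", "ει", "οι"
  )
}

sim_codas <- function() c("", "ς", "ν")

# generator-side letter -> phone map (the generative gold, independent of the
# package's full context-rule engine; the generator only produces contexts this
# map covers: onset clusters before a vowel, single final ς/ν codas)
sim_syllable_phones <- function(onset, nucleus, coda) {
  vmap <- c(
    "α" = "a", "ε" = "ε", "η" = "i", "ι" = "i", "υ" = "i", "ο" = "o",
    "ω" = "o", "ου" = "u", "αι" = "ε", "ει" = "i", "οι" = "i"
  )
  cmap <- c(
    "β" = "v", "γ" = "γ", "δ" = "δ", "ζ" = "z", "θ" = "θ", "κ" = "k",
    "λ" = "l", "μ" = "m", "ν" = "n", "π" = "p", "ρ" = "r", "σ" = "s",
    "τ" = "t", "φ" = "f", "χ" = "x"
  )
  v <- unname(vmap[[nucleus]])
  on <- character(0)
  if (nzchar(onset)) {
    letters_on <- gk_chars(onset)
    on <- unlist(lapply(letters_on, function(l) {
      switch(l,
        "ξ" = c("k", "s"),
        "ψ" = c("p", "s"),
        unname(cmap[[l]])
      )
    }))
    if (v %in% c("ε", "i")) { # velar palatalization before front vowels
      last <- length(on)
      pal <- c("k" = "c", "γ" = "ʝ", "x" = "ç")
      if (on[last] %in% names(pal)) on[last] <- unname(pal[[on[last]]])
    }
  }
  cd <- switch(coda, "ς" = "s", "ν" = "n", character(0))
  list(phones = c(on, v, cd), vowel_at = length(on) + 1L)
}

sim_accent_nucleus <- function(nucleus) {
  ch <- gk_chars(nucleus)
  ch[length(ch)] <- gk_tonos_map[[ch[length(ch)]]]
  paste(ch, collapse = "")
}

#' Generate a synthetic Greek-like lexicon
#'
#' Produces `n_words` unique words with gold annotations: every word is built
#' from legal syllable parts (so it passes both syllabifiers and the recovered
#' parse equals the generative one), the tonos falls within the final three
#' syllables, each polysyllable's stress position equals its ending's modal
#' position with probability `theta`, token counts follow a rank-frequency
#' power law, and each word carries a PoS label whose category-specific stress
#' profile shapes the ending inventory.
#'
#' @param n_words Number of unique words.
#' @param theta Ending-stress consistency: probability that a word is stressed
#'   on its ending's modal position (in `[0.5, 1]`).
#' @param seed Optional integer seed; the generator is reproducible given the
#'   seed and leaves the caller's RNG state untouched.
#' @param syllable_dist Named numeric vector of syllable-count probabilities
#'   (support 1-7); the default follows the lemma-type length distribution of
#'   the Greek lexicon.
#' @param zipf_exponent Exponent of the within-length rank-frequency power law.
#' @param count_total Total token budget distributed over the lexicon.
#' @param length_token_share Named numeric vector: share of the token budget
#'   carried by each syllable-length class. The default mirrors the token
#'   distribution by length of the emulated lexicon, where monosyllables are
#'   under 1% of types but over half of all tokens.
#' @param n_endings Size of the ending inventory.
#' @param pos_mix Named probabilities for PoS categories.
#' @param pos_profiles Named list: per-category probability over stress
#'   positions 1 (final), 2 (pre-final), 3 (antepenultimate) used when drawing
#'   each ending's modal position. Adjectives disfavour the pre-final position.
#' @param length_weights 3-column matrix (positions 1-3) of per-length
#'   preference weights used when a word of a given syllable count draws an
#'   ending: rows named by length, last row applying to all longer words.
#' @return A lexicon tibble with columns `word`, `freq_count`, `pos_primary`,
#'   `ending_id`, `gold_ending`, `gold_modal_position`, `gold_stress_position`,
#'   `gold_n_syll`, `gold_orth_syll`, `gold_transcription`, `gold_phon_syll`.
#' @examples
#' simulate_lexicon(50, theta = 1, seed = 1)
#' @export
simulate_lexicon <- function(n_words = 10000,
                             theta = 0.9,
                             seed = NULL,
                             syllable_dist = c(
                               "1" = 0.008, "2" = 0.104, "3" = 0.238,
                               "4" = 0.302, "5" = 0.222, "6" = 0.093,
                               "7" = 0.026
                             ),
                             zipf_exponent = 1,
                             count_total = 421000,
                             length_token_share = c(
                               "1" = 0.535, "2" = 0.239, "3" = 0.104,
                               "4" = 0.079, "5" = 0.033, "6" = 0.010,
                               "7" = 0.001
                             ),
                             n_endings = 60,
                             pos_mix = c(
                               noun = 0.585, adjective = 0.258,
                               verb = 0.142, adverb = 0.015
                             ),
                             pos_profiles = list(
                               noun = c(0.20, 0.45, 0.35),
                               adjective = c(0.35, 0.15, 0.50),
                               verb = c(0.25, 0.45, 0.30),
                               adverb = c(0.30, 0.40, 0.30)
                             ),
                             length_weights = rbind(
                               "2" = c(0.35, 0.65, 0),
                               "3" = c(0.25, 0.45, 0.30),
                               "4" = c(0.15, 0.30, 0.55)
                             )) {
  stopifnot(n_words >= 1, theta >= 0.5, theta <= 1)
  stopifnot(all(names(pos_mix) %in% names(pos_profiles)))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  syllable_dist <- syllable_dist / sum(syllable_dist)
  lengths_support <- as.integer(names(syllable_dist))

  onsets <- sim_onsets()
  nuclei <- sim_nuclei()
  codas <- sim_codas()

  # ending inventory: (PoS category, modal position, pre-final nucleus, final
  # syllable); distinct Colombo ending strings
  endings <- NULL
  tries <- 0L
  while (is.null(endings) ||
    (nrow(endings) < n_endings && tries < 40L)) {
    tries <- tries + 1L
    cand <- tibble::tibble(
      category = sample(names(pos_mix), n_endings, replace = TRUE, prob = pos_mix),
      prefinal_nucleus = sample(nuclei, n_endings, replace = TRUE),
      final_onset = sample(onsets, n_endings, replace = TRUE),
      final_nucleus = sample(nuclei, n_endings, replace = TRUE),
      final_coda = sample(codas, n_endings, replace = TRUE,
        prob = c(0.55, 0.35, 0.10)
      )
    )
    cand$modal <- vapply(cand$category, function(cat) {
      sample(1:3, 1, prob = pos_profiles[[cat]])
    }, integer(1))
    cand$final_syll <- paste0(cand$final_onset, cand$final_nucleus, cand$final_coda)
    cand$ending <- paste0(cand$prefinal_nucleus, cand$final_syll)
    endings <- dplyr::bind_rows(endings, cand) |>
      dplyr::distinct(.data$ending, .keep_all = TRUE)
  }
  endings <- endings[seq_len(min(nrow(endings), n_endings)), ]
  endings$ending_id <- seq_len(nrow(endings))
  # every category and every modal position reachable by disyllables
  if (!any(endings$modal <= 2L)) {
    endings$modal[1] <- 2L
  }

  len_pref <- function(L) {
    key <- as.character(min(L, max(as.integer(rownames(length_weights)))))
    length_weights[key, ]
  }

  make_word <- function(L) {
    if (L == 1L) {
      onset <- sample(onsets, 1)
      nucleus <- sample(nuclei, 1)
      coda <- sample(codas, 1, prob = c(0.45, 0.35, 0.20))
      sylls <- list(c(onset = onset, nucleus = nucleus, coda = coda))
      return(list(
        sylls = sylls, stress = NA_integer_, position = 0L,
        ending_id = NA_integer_, ending = NA_character_,
        modal = NA_integer_,
        category = sample(names(pos_mix), 1, prob = pos_mix)
      ))
    }
    pref <- len_pref(L)
    w <- pref[endings$modal]
    if (all(w == 0)) w <- rep(1, nrow(endings))
    e <- endings[sample.int(nrow(endings), 1, prob = w), ]
    valid <- seq_len(min(3L, L))
    position <- if (stats::runif(1) < theta || length(valid) == 1L) {
      e$modal
    } else {
      alt <- setdiff(valid, e$modal)
      if (length(alt) == 1L) alt else sample(alt, 1)
    }
    sylls <- vector("list", L)
    for (k in seq_len(L - 2L)) {
      sylls[[k]] <- c(
        onset = sample(onsets, 1),
        nucleus = sample(nuclei, 1), coda = ""
      )
    }
    sylls[[L - 1L]] <- c(
      onset = sample(onsets, 1),
      nucleus = e$prefinal_nucleus, coda = ""
    )
    sylls[[L]] <- c(
      onset = e$final_onset, nucleus = e$final_nucleus,
      coda = e$final_coda
    )
    list(
      sylls = sylls, stress = L - position + 1L, position = as.integer(position),
      ending_id = e$ending_id, ending = e$ending, modal = e$modal,
      category = e$category
    )
  }

  render <- function(wd) {
    units <- vapply(seq_along(wd$sylls), function(k) {
      s <- wd$sylls[[k]]
      nucleus <- if (!is.na(wd$stress) && k == wd$stress) {
        sim_accent_nucleus(s[["nucleus"]])
      } else {
        s[["nucleus"]]
      }
      paste0(s[["onset"]], nucleus, s[["coda"]])
    }, character(1))
    phones <- character(0)
    stress_phone <- NA_integer_
    unit_phones <- vector("list", length(wd$sylls))
    for (k in seq_along(wd$sylls)) {
      s <- wd$sylls[[k]]
      sp <- sim_syllable_phones(s[["onset"]], s[["nucleus"]], s[["coda"]])
      unit_phones[[k]] <- sp$phones
      if (!is.na(wd$stress) && k == wd$stress) {
        stress_phone <- length(phones) + sp$vowel_at
      }
      phones <- c(phones, sp$phones)
    }
    list(
      word = paste(units, collapse = ""),
      orth_syll = paste(units, collapse = "-"),
      phon_units = vapply(unit_phones, paste, character(1), collapse = ""),
      transcription = paste(phones, collapse = ""),
      stress_phone = stress_phone
    )
  }

  lengths <- sample(lengths_support, n_words, replace = TRUE, prob = syllable_dist)
  word <- character(n_words)
  pos_primary <- character(n_words)
  ending_id <- integer(n_words)
  gold_ending <- character(n_words)
  gold_modal_position <- integer(n_words)
  gold_stress_position <- integer(n_words)
  gold_n_syll <- integer(n_words)
  gold_orth_syll <- character(n_words)
  gold_transcription <- character(n_words)
  gold_phon_syll <- character(n_words)

  seen <- new.env(hash = TRUE, parent = emptyenv())
  filled <- 0L
  attempts <- 0L
  max_attempts <- 30L * n_words
  i <- 1L
  while (filled < n_words) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(
        "generation error: could not assemble ", n_words,
        " unique words; the configuration is combinatorially infeasible",
        call. = FALSE
      )
    }
    wd <- make_word(lengths[i])
    r <- render(wd)
    if (!is.null(seen[[r$word]])) next
    seen[[r$word]] <- TRUE
    filled <- filled + 1L
    word[filled] <- r$word
    pos_primary[filled] <- wd$category
    ending_id[filled] <- wd$ending_id
    gold_ending[filled] <- wd$ending
    gold_modal_position[filled] <- wd$modal
    gold_stress_position[filled] <- wd$position
    gold_n_syll[filled] <- length(wd$sylls)
    gold_orth_syll[filled] <- r$orth_syll
    gold_transcription[filled] <- r$transcription
    gold_phon_syll[filled] <- paste(r$phon_units, collapse = "-")
    i <- if (i == n_words) 1L else i + 1L
  }
  # token mass: each syllable-length class gets its share of the budget, and
  # ranks within a class follow the configured power law
  length_token_share <- length_token_share / sum(length_token_share)
  freq_count <- numeric(n_words)
  for (L in unique(gold_n_syll)) {
    idx <- which(gold_n_syll == L)
    share <- length_token_share[as.character(L)]
    if (is.na(share)) share <- min(length_token_share)
    r <- sample.int(length(idx), length(idx))
    w_raw <- r^(-zipf_exponent)
    freq_count[idx] <- pmax(1, round(count_total * share * w_raw / sum(w_raw)))
  }
  tibble::tibble(
    word = word,
    freq_count = freq_count,
    pos_primary = pos_primary,
    ending_id = ending_id,
    gold_ending = gold_ending,
    gold_modal_position = gold_modal_position,
    gold_stress_position = gold_stress_position,
    gold_n_syll = gold_n_syll,
    gold_orth_syll = gold_orth_syll,
    gold_transcription = gold_transcription,
    gold_phon_syll = gold_phon_syll
  )
}
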