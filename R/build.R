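# End-to-end pipeline: word + frequency list in, fully annotated lexicon table
# out. Per-word failures are captured in an `error` column; the pipeline never
# aborts on a single bad word.

#' Pipeline configuration
#'
#' @param onsets Attested onset inventory for the orthographic syllabifier.
#' @param rules [cluster_rules()] for the phonological syllabifier.
#' @param civ [civ_policy()] for ambiguous CiV sites.
#' @param corpus_millions,types_millions Zipf denominator constants, see
#'   [zipf()]. `corpus_millions` also drives frequency per million.
#' @param keep_nasals Keep nasal + homorganic stop sequences in transcriptions.
#' @param pos_dictionary Optional PoS dictionary for [pos_annotate()].
#' @param old20_k Neighbourhood size for [old20()].
#' @param tie_break Stress-prediction tie-break order.
#' @return A list of class `lexicon_config`.
#' @export
lexicon_config <- function(onsets = greek_onsets(),
                           rules = default_cluster_rules(),
                           civ = default_civ_policy(),
                           corpus_millions = 46.89,
                           types_millions = 0.0353,
                           keep_nasals = FALSE,
                           pos_dictionary = NULL,
                           old20_k = 20,
                           tie_break = c(2L, 3L, 1L)) {
  structure(
    list(
      onsets = onsets, rules = rules, civ = civ,
      corpus_millions = corpus_millions, types_millions = types_millions,
      keep_nasals = keep_nasals, pos_dictionary = pos_dictionary,
      old20_k = old20_k, tie_break = tie_break
    ),
    class = "lexicon_config"
  )
}

#' Build a fully annotated lexicon table
#'
#' Runs every annotation stage over a word + frequency-count table:
#' normalization, orthographic syllabification with CiV disambiguation,
#' grapheme-to-phoneme transcription, nasal simplification, phonological
#' (maximal-onset) syllabification, stress position, rime and Colombo ending,
#' Zipf and per-million frequency, Coltheart's N and OLD20/PLD20 (stressed and
#' unstressed variants), rime and stress neighbourhood, syllable frequencies,
#' and optional PoS tags. Deterministic given the configuration.
#'
#' @param wordfreq A data frame with columns `word` and `freq_count`
#'   (non-negative token counts).
#' @param config A [lexicon_config()].
#' @return A tibble with one row per input word. Words that fail a per-word
#'   stage carry the failure message in the `error` column and `NA` annotations;
#'   corpus-level metrics are computed over the error-free rows. OLD20/PLD20
#'   are `NA` (with a warning) when the lexicon has fewer candidates than
#'   `old20_k`.
#' @examples
#' \donttest{
#' wf <- tibble::tibble(word = c("γέρος", "πατέρας", "θάλασσα"), freq_count = c(10, 5, 2))
#' build_lexicon(wf)
#' }
#' @export
build_lexicon <- function(wordfreq, config = lexicon_config()) {
  stopifnot(all(c("word", "freq_count") %in% names(wordfreq)))
  if (any(wordfreq$freq_count < 0)) stop("negative frequency count", call. = FALSE)
  if (nrow(wordfreq) == 0L) {
    return(tibble::tibble(word = character(), freq_count = numeric()))
  }

  per_word <- purrr::map(wordfreq$word, function(w) {
    tryCatch(
      {
        w <- normalize_greek(w)
        orth <- syllabify_orth(w, onsets = config$onsets, civ = config$civ)
        pseq <- g2p(w, civ = config$civ, keep_nasals = config$keep_nasals)
        phon <- syllabify_phon(pseq, rules = config$rules)
        pos <- stress_position(orth)
        stressed <- gk_is_stressed(w)
        list(
          word = w,
          orth_syll = as.character(orth),
          n_syll = n_syllables(orth),
          transcription = format(pseq),
          phon_plain = paste(pseq$phones, collapse = ""),
          phon_syll = format(phon),
          n_syll_phon = n_syllables(phon),
          stress_position = pos,
          rime = if (stressed) rime(w) else NA_character_,
          ending = if (n_syllables(orth) >= 2) colombo_ending(w, orth) else NA_character_,
          error = NA_character_
        )
      },
      error = function(e) {
        list(
          word = w, orth_syll = NA_character_, n_syll = NA_integer_,
          transcription = NA_character_, phon_plain = NA_character_,
          phon_syll = NA_character_, n_syll_phon = NA_integer_,
          stress_position = NA_integer_, rime = NA_character_,
          ending = NA_character_, error = conditionMessage(e)
        )
      }
    )
  })

  lex <- dplyr::bind_cols(
    tibble::as_tibble(purrr::map_dfr(per_word, tibble::as_tibble)),
    tibble::tibble(freq_count = wordfreq$freq_count)
  )
  lex <- dplyr::relocate(lex, "freq_count", .after = "word")

  lex$fpm <- lex$freq_count / config$corpus_millions
  lex$zipf <- zipf(lex$freq_count, config$corpus_millions, config$types_millions)

  ok <- is.na(lex$error)
  words_s <- lex$word[ok]
  words_u <- strip_stress(words_s)
  phon_s <- lex$transcription[ok] # stress marker kept, like the tonos
  phon_u <- lex$phon_plain[ok]

  lex$coltheart_n_stressed <- NA_integer_
  lex$coltheart_n_unstressed <- NA_integer_
  lex$coltheart_n_stressed[ok] <- coltheart_n(words_s, words_s)
  lex$coltheart_n_unstressed[ok] <- coltheart_n(words_u, words_u)

  lex$old20_stressed <- NA_real_
  lex$old20_unstressed <- NA_real_
  lex$pld20_stressed <- NA_real_
  lex$pld20_unstressed <- NA_real_
  if (sum(ok) > config$old20_k) {
    lex$old20_stressed[ok] <- old20(words_s, words_s, k = config$old20_k)
    lex$old20_unstressed[ok] <- old20(words_u, words_u, k = config$old20_k)
    lex$pld20_stressed[ok] <- old20(phon_s, phon_s, k = config$old20_k)
    lex$pld20_unstressed[ok] <- old20(phon_u, phon_u, k = config$old20_k)
  } else {
    warning(
      "fewer than old20_k + 1 well-formed entries; OLD20/PLD20 set to NA",
      call. = FALSE
    )
  }

  lex$rime_n <- rime_neighbourhood(lex)
  lex <- annotate_stress_neighbourhood(lex)

  for (u in c("orth", "phon")) {
    for (s in c(TRUE, FALSE)) {
      tbl <- syllable_frequencies(lex[ok, ], unit = u, stressed = s)
      colname <- paste0("mean_syll_freq_", u, if (s) "_stressed" else "_unstressed")
      lex[[colname]] <- NA_real_
      lex[[colname]][ok] <- mean_syllable_frequency(lex[ok, ], tbl, unit = u, stressed = s)
    }
  }

  if (!is.null(config$pos_dictionary)) {
    lex <- pos_annotate(lex, config$pos_dictionary)
  }
  lex
}
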