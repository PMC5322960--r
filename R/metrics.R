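# Frequency and similarity metrics. Similarity metrics treat the word-final
# sigma allograph (ς) as identical to σ; callers choose stressed vs unstressed
# preprocessing by passing tonos-bearing or strip_stress()ed strings.

gk_metric_form <- function(x) gsub("ς", "σ", x, fixed = TRUE)

#' Zipf-scale word frequency
#'
#' `log10((count + 1) / (corpus_millions + types_millions)) + 3`: the base-10
#' logarithm of the Laplace-smoothed frequency per million plus 3, so that a
#' value of 3 marks one occurrence per million and the scale midpoint separates
#' low- from high-frequency words. The default denominator constants are a
#' 46.89-million-token corpus with 0.0353 million unique types.
#'
#' @param count Non-negative token frequency count(s).
#' @param corpus_millions Corpus size in millions of tokens.
#' @param types_millions Number of unique word types, in millions.
#' @return Numeric vector of Zipf values.
#' @examples
#' zipf(0)
#' zipf(999, corpus_millions = 1, types_millions = 0.001)
#' @export
zipf <- function(count, corpus_millions = 46.89, types_millions = 0.0353) {
  stopifnot(corpus_millions > 0, types_millions > 0)
  if (any(count < 0)) stop("negative frequency count", call. = FALSE)
  log10((count + 1) / (corpus_millions + types_millions)) + 3
}

#' Levenshtein edit distance
#'
#' Unit-cost insertions, deletions and substitutions, computed with
#' [utils::adist()]. Final sigma is treated as sigma.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @examples
#' levenshtein("αρμα", "αρπα")
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(gk_metric_form(a), gk_metric_form(b))
  if (length(a) == length(b) || length(a) == 1 || length(b) == 1) {
    n <- max(length(a), length(b))
    return(as.integer(d[cbind(
      rep_len(seq_along(a), n),
      rep_len(seq_along(b), n)
    )]))
  }
  stop("a and b must be recyclable to a common length", call. = FALSE)
}

#' Coltheart's N orthographic neighbourhood
#'
#' Number of lexicon entries of the same length at Hamming distance exactly one
#' (single-letter substitution). The word itself is never counted.
#'
#' @param words Character vector of target words.
#' @param lexicon Character vector of lexicon entries (deduplicated
#'   internally). Stress handling is the caller's choice: pass stressed or
#'   [strip_stress()]ed strings consistently.
#' @return Integer vector of neighbour counts.
#' @examples
#' coltheart_n("μέρος", c("γέρος", "μέρος", "μέλος"))
#' @export
coltheart_n <- function(words, lexicon) {
  lex <- unique(gk_metric_form(lexicon))
  lex_len <- nchar(lex)
  w <- gk_metric_form(words)
  vapply(w, function(x) {
    cand <- lex[lex_len == nchar(x) & lex != x]
    if (length(cand) == 0L) {
      return(0L)
    }
    sum(utils::adist(x, cand)[1, ] == 1L)
  }, integer(1), USE.NAMES = FALSE)
}

#' OLD20 / PLD20 similarity
#'
#' Mean Levenshtein distance to the 20 closest other entries in the lexicon
#' (self excluded). Applied to orthographic strings this is OLD20; applied to
#' transcription strings it is PLD20. Fewer than `k` candidate entries is an
#' error, not a silent partial mean.
#'
#' @inheritParams coltheart_n
#' @param k Number of closest neighbours to average (default 20).
#' @return Numeric vector of mean distances.
#' @export
old20 <- function(words, lexicon, k = 20) {
  lex <- unique(gk_metric_form(lexicon))
  w <- gk_metric_form(words)
  vapply(w, function(x) {
    cand <- lex[lex != x]
    if (length(cand) < k) {
      stop(
        "insufficient lexicon: ", length(cand), " candidate(s) for k = ", k,
        call. = FALSE
      )
    }
    d <- utils::adist(x, cand)[1, ]
    mean(sort(d, partial = k)[seq_len(k)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rime of a stressed word
#'
#' The letter string from the stressed vowel (inclusive) to the final letter,
#' stress-stripped. An unstressed polysyllable has no defined rime and raises
#' an error; for unstressed monosyllables see the caller's conventions.
#'
#' @param x Character vector of normalized, tonos-bearing words.
#' @return Character vector of rime strings.
#' @examples
#' rime("γέρος")
#' rime("καμβάς")
#' @export
rime <- function(x) {
  idx <- stressed_vowel_index(x)
  if (any(is.na(idx))) {
    stop(
      "missing stress: no tonos in word \"", x[which(is.na(idx))[1]], "\"",
      call. = FALSE
    )
  }
  strip_stress(stringr::str_sub(x, idx))
}

#' Colombo stress-neighbourhood ending
#'
#' The orthographic ending from the first letter of the pre-final syllable's
#' vowel-grapheme nucleus up to the final letter, with stress diacritics
#' omitted. Defined for words of at least two syllables.
#'
#' @param word A normalized Greek word (single string).
#' @param syllables Its orthographic [syllabification()]; computed via
#'   [syllabify_orth()] when omitted.
#' @param ... Passed to [syllabify_orth()] when `syllables` is missing.
#' @return The ending string.
#' @examples
#' colombo_ending("γέρος")
#' @export
colombo_ending <- function(word, syllables = NULL, ...) {
  stopifnot(is.character(word), length(word) == 1)
  if (is.null(syllables)) syllables <- syllabify_orth(word, ...)
  stopifnot(inherits(syllables, "gk_syllables"))
  units <- syllables$units
  n <- length(units)
  if (n < 2L) {
    stop("undefined ending: \"", word, "\" is monosyllabic", call. = FALSE)
  }
  prefinal <- units[n - 1L]
  # nucleus = last vowel-grapheme group of the pre-final unit: in glide-merged
  # units (synizesis, e.g. γυά) the i-element is not the nucleus vowel
  toks <- gk_tokenize(prefinal)
  v_at <- which(toks$type == "vowel")
  v <- toks$start[v_at[length(v_at)]]
  offset <- sum(nchar(units[seq_len(n - 2L)])) + v
  strip_stress(stringr::str_sub(paste(units, collapse = ""), offset))
}

#' Stress neighbourhood index of a lexicon
#'
#' Groups polysyllabic entries by their Colombo ending and tabulates type and
#' token counts by stress position, with proportions normalized within each
#' ending (types and tokens separately). The target entry is included in its
#' own ending group.
#'
#' @param lexicon A data frame with columns `ending`, `stress_position` and
#'   `freq_count` (see [build_lexicon()]).
#' @return A tibble with columns `ending`, `stress_position`, `n_type`,
#'   `n_token`, `prop_type`, `prop_token`.
#' @seealso [annotate_stress_neighbourhood()]
#' @export
stress_neighbourhood <- function(lexicon) {
  stopifnot(all(c("ending", "stress_position", "freq_count") %in% names(lexicon)))
  lexicon |>
    dplyr::filter(!is.na(.data$ending), !is.na(.data$stress_position)) |>
    dplyr::count(.data$ending, .data$stress_position,
      wt = NULL, name = "n_type"
    ) |>
    dplyr::left_join(
      lexicon |>
        dplyr::filter(!is.na(.data$ending), !is.na(.data$stress_position)) |>
        dplyr::group_by(.data$ending, .data$stress_position) |>
        dplyr::summarise(n_token = sum(.data$freq_count), .groups = "drop"),
      by = c("ending", "stress_position")
    ) |>
    dplyr::group_by(.data$ending) |>
    dplyr::mutate(
      prop_type = .data$n_type / sum(.data$n_type),
      prop_token = .data$n_token / sum(.data$n_token)
    ) |>
    dplyr::ungroup()
}

#' Annotate entries with their stress-neighbourhood proportions
#'
#' Adds, for each polysyllabic entry, the proportion of its ending group (types
#' and tokens) sharing its own stress position.
#'
#' @inheritParams stress_neighbourhood
#' @param groups Optional precomputed [stress_neighbourhood()] index.
#' @return The lexicon with columns `stress_nbhd_type_prop`,
#'   `stress_nbhd_token_prop` added.
#' @export
annotate_stress_neighbourhood <- function(lexicon, groups = NULL) {
  if (is.null(groups)) groups <- stress_neighbourhood(lexicon)
  lexicon |>
    dplyr::left_join(
      dplyr::select(groups, "ending", "stress_position",
        stress_nbhd_type_prop = "prop_type",
        stress_nbhd_token_prop = "prop_token"
      ),
      by = c("ending", "stress_position")
    )
}

#' Rime neighbourhood counts
#'
#' For each stressed polysyllabic entry, the number of other entries whose rime
#' string and stress position both match (self excluded).
#'
#' @param lexicon A data frame with columns `rime` and `stress_position`.
#' @return Integer vector aligned with the rows of `lexicon` (`NA` where the
#'   rime is undefined).
#' @export
rime_neighbourhood <- function(lexicon) {
  stopifnot(all(c("rime", "stress_position") %in% names(lexicon)))
  key <- paste(lexicon$rime, lexicon$stress_position, sep = "\r")
  key[is.na(lexicon$rime) | is.na(lexicon$stress_position)] <- NA
  tab <- table(key)
  out <- as.integer(tab[key]) - 1L
  out[is.na(key)] <- NA_integer_
  out
}

#' Syllable frequency tables
#'
#' Type counts, token counts and per-million rates over all syllable slots of a
#' lexicon, for orthographic or phonological units, keeping or stripping the
#' stress mark.
#'
#' @param lexicon A data frame with columns `freq_count` and the syllable
#'   column named by `unit` (`orth_syll` or `phon_syll`, hyphen-joined units).
#' @param unit `"orth"` or `"phon"`.
#' @param stressed Keep the tonos / stress mark on the units (`TRUE`) or strip
#'   it before counting (`FALSE`).
#' @param corpus_size Total token count used for per-million rates; defaults to
#'   `sum(lexicon$freq_count)`.
#' @return A tibble with columns `syllable`, `n_type`, `n_token`, `per_million`.
#' @seealso [mean_syllable_frequency()]
#' @export
syllable_frequencies <- function(lexicon, unit = c("orth", "phon"),
                                 stressed = TRUE, corpus_size = NULL) {
  unit <- match.arg(unit)
  col <- paste0(unit, "_syll")
  stopifnot(all(c(col, "freq_count") %in% names(lexicon)))
  if (is.null(corpus_size)) corpus_size <- sum(lexicon$freq_count)
  sylls <- stringr::str_split(lexicon[[col]], "-")
  tbl <- tibble::tibble(
    syllable = unlist(sylls),
    freq_count = rep(lexicon$freq_count, lengths(sylls))
  )
  if (!stressed) {
    tbl$syllable <- strip_stress(stringr::str_remove(tbl$syllable, "'"))
  }
  tbl |>
    dplyr::group_by(.data$syllable) |>
    dplyr::summarise(
      n_type = dplyr::n(),
      n_token = sum(.data$freq_count),
      .groups = "drop"
    ) |>
    dplyr::mutate(per_million = .data$n_token / corpus_size * 1e6) |>
    dplyr::arrange(dplyr::desc(.data$n_token))
}

#' Per-entry mean syllable frequency
#'
#' Mean of the (type or token) frequencies of an entry's syllables, from a
#' [syllable_frequencies()] table.
#'
#' @inheritParams syllable_frequencies
#' @param table A [syllable_frequencies()] table for the same lexicon.
#' @param weighting `"type"` or `"token"` frequencies.
#' @return Numeric vector aligned with the rows of `lexicon`.
#' @export
mean_syllable_frequency <- function(lexicon, table, unit = c("orth", "phon"),
                                    stressed = TRUE,
                                    weighting = c("token", "type")) {
  unit <- match.arg(unit)
  weighting <- match.arg(weighting)
  col <- paste0(unit, "_syll")
  val <- stats::setNames(
    table[[paste0("n_", weighting)]],
    table$syllable
  )
  vapply(stringr::str_split(lexicon[[col]], "-"), function(s) {
    if (!stressed) s <- strip_stress(stringr::str_remove(s, "'"))
    mean(val[s], na.rm = FALSE)
  }, numeric(1))
}
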