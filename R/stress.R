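# Stress-position extraction, ending-based stress prediction (two procedures:
# Colombo-ending majority and longest-attested-rime hierarchy), accuracy
# evaluation and distribution tables.
#
# Numeric coding, counted from the word end: 1 = final, 2 = pre-final,
# 3 = antepenultimate, k > 3 = earlier (flagged; not reachable for tonos-marked
# Greek, where stress falls within the final three syllables). Monosyllables
# are coded 0 and excluded from prediction.

gk_stress_levels <- c("monosyllable", "final", "pre-final", "antepenultimate", "earlier")

#' Stress position of a syllabified word
#'
#' @param x A `gk_syllables` object.
#' @return Integer: 0 for monosyllables, otherwise the distance of the stressed
#'   syllable from the word end (1 = final). A polysyllable without a stressed
#'   unit raises a missing-stress error.
#' @examples
#' stress_position(syllabify_orth("πατέρας"))
#' @seealso [stress_label()]
#' @export
stress_position <- function(x) {
  stopifnot(inherits(x, "gk_syllables"))
  n <- length(x$units)
  if (n == 1L) {
    return(0L)
  }
  if (is.na(x$stressed)) {
    stop("missing stress: polysyllable with no stressed unit", call. = FALSE)
  }
  n - x$stressed + 1L
}

#' Label a numeric stress position
#'
#' @param position Integer vector: 0 (monosyllable), 1 (final), 2 (pre-final),
#'   3 (antepenultimate), >3 (earlier).
#' @return Factor with levels monosyllable, final, pre-final, antepenultimate,
#'   earlier.
#' @export
stress_label <- function(position) {
  lab <- dplyr::case_when(
    position == 0L ~ "monosyllable",
    position == 1L ~ "final",
    position == 2L ~ "pre-final",
    position == 3L ~ "antepenultimate",
    position > 3L ~ "earlier"
  )
  factor(lab, levels = gk_stress_levels)
}

# modal position of a counts-by-position vector with the deterministic
# tie-break pre-final > antepenultimate > final (> earlier), the corpus-global
# frequency order
gk_modal_position <- function(positions, counts, tie_break = c(2L, 3L, 1L)) {
  stopifnot(length(positions) == length(counts))
  tie_rank <- match(positions, tie_break)
  tie_rank[is.na(tie_rank)] <- length(tie_break) + positions[is.na(tie_rank)]
  ord <- order(-counts, tie_rank)
  positions[ord[1]]
}

#' Ending-group stress index
#'
#' Tabulates type and token counts by stress position within each Colombo
#' ending group of a lexicon — the index consumed by
#' [predict_stress_ending()].
#'
#' @param lexicon A data frame with columns `ending`, `stress_position`,
#'   `freq_count`; monosyllables (position 0) are ignored.
#' @return A tibble with columns `ending`, `stress_position`, `n_type`,
#'   `n_token`.
#' @export
ending_index <- function(lexicon) {
  stopifnot(all(c("ending", "stress_position", "freq_count") %in% names(lexicon)))
  lexicon |>
    dplyr::filter(
      !is.na(.data$ending), !is.na(.data$stress_position),
      .data$stress_position > 0L
    ) |>
    dplyr::group_by(.data$ending, .data$stress_position) |>
    dplyr::summarise(
      n_type = dplyr::n(),
      n_token = sum(.data$freq_count),
      .groups = "drop"
    )
}

#' Rime stress index
#'
#' Type and token counts by stress position for every rime string occurring in
#' a lexicon — the index consumed by [predict_stress_rime()].
#'
#' @param lexicon A data frame with columns `rime`, `stress_position`,
#'   `freq_count`; monosyllables are ignored.
#' @return A tibble with columns `rime`, `stress_position`, `n_type`, `n_token`.
#' @export
rime_index <- function(lexicon) {
  stopifnot(all(c("rime", "stress_position", "freq_count") %in% names(lexicon)))
  lexicon |>
    dplyr::filter(
      !is.na(.data$rime), !is.na(.data$stress_position),
      .data$stress_position > 0L
    ) |>
    dplyr::group_by(.data$rime, .data$stress_position) |>
    dplyr::summarise(
      n_type = dplyr::n(),
      n_token = sum(.data$freq_count),
      .groups = "drop"
    )
}

#' Predict stress position from the Colombo ending
#'
#' Assigns each word the stress position most frequent among the entries
#' sharing its orthographic ending, by type counts or token frequency mass.
#' Ties break deterministically pre-final > antepenultimate > final.
#'
#' @param endings Character vector of Colombo endings (see [colombo_ending()]).
#' @param index An [ending_index()] table.
#' @param weighting `"type"` or `"token"`.
#' @param tie_break Integer vector giving the tie-break preference order.
#' @return Integer vector of predicted positions; `NA` where the ending is not
#'   attested in the index (no-prediction signal).
#' @export
predict_stress_ending <- function(endings, index, weighting = c("type", "token"),
                                  tie_break = c(2L, 3L, 1L)) {
  weighting <- match.arg(weighting)
  wcol <- paste0("n_", weighting)
  modes <- index |>
    dplyr::group_by(.data$ending) |>
    dplyr::summarise(
      mode = gk_modal_position(.data$stress_position, .data[[wcol]], tie_break),
      .groups = "drop"
    )
  modes$mode[match(endings, modes$ending)]
}

#' Predict stress position from the longest attested rime
#'
#' Scans the word's stress-stripped suffixes from longest to shortest; the
#' first suffix attested as a rime in the index yields its modal stress
#' position (same tie-break as [predict_stress_ending()]).
#'
#' @param words Character vector of normalized words.
#' @param index A [rime_index()] table.
#' @inheritParams predict_stress_ending
#' @return Integer vector of predicted positions; `NA` where no suffix is
#'   attested.
#' @export
predict_stress_rime <- function(words, index, weighting = c("type", "token"),
                                tie_break = c(2L, 3L, 1L)) {
  weighting <- match.arg(weighting)
  wcol <- paste0("n_", weighting)
  modes <- index |>
    dplyr::group_by(.data$rime) |>
    dplyr::summarise(
      mode = gk_modal_position(.data$stress_position, .data[[wcol]], tie_break),
      .groups = "drop"
    )
  lookup <- stats::setNames(modes$mode, modes$rime)
  vapply(strip_stress(words), function(w) {
    n <- nchar(w)
    for (i in seq_len(n)) {
      hit <- lookup[stringr::str_sub(w, i)]
      if (!is.na(hit)) {
        return(as.integer(hit))
      }
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

#' Evaluate ending-based stress prediction on a lexicon
#'
#' Predicts the stress position of every polysyllabic entry from its Colombo
#' ending (majority procedure) or its longest attested rime (hierarchy
#' procedure), with the indices built from the same lexicon (the target entry
#' is included in its own group), and scores the proportion of entries (types)
#' and of frequency mass (tokens) stressed correctly. Monosyllables never
#' contribute. An unpredicted entry, or a predicted position exceeding the
#' entry's syllable count, counts as incorrect.
#'
#' @param lexicon A data frame with columns `word`, `ending`, `rime`,
#'   `stress_position`, `n_syll`, `freq_count` (see [build_lexicon()]).
#' @param method `"ending"` or `"rime"`.
#' @param weighting `"type"` or `"token"` — which counts drive the modal
#'   position within each group. Accuracies are always reported both ways.
#' @param tie_break Tie-break preference order over positions.
#' @return An object of class `stress_eval`: accuracies (type and token), the
#'   confusion table, method and weighting. Supports [tidy()] (confusion table)
#'   and [glance()] (one-row accuracy summary).
#' @export
evaluate_stress_prediction <- function(lexicon,
                                       method = c("ending", "rime"),
                                       weighting = c("type", "token"),
                                       tie_break = c(2L, 3L, 1L)) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  poly <- dplyr::filter(
    lexicon,
    !is.na(.data$stress_position), .data$stress_position > 0L
  )
  if (nrow(poly) == 0L) {
    stop("no polysyllabic entries: accuracy undefined", call. = FALSE)
  }
  predicted <- switch(method,
    ending = predict_stress_ending(
      poly$ending, ending_index(poly),
      weighting = weighting, tie_break = tie_break
    ),
    rime = predict_stress_rime(
      poly$word, rime_index(poly),
      weighting = weighting, tie_break = tie_break
    )
  )
  correct <- !is.na(predicted) &
    predicted == poly$stress_position &
    predicted <= poly$n_syll
  structure(
    list(
      accuracy_type = mean(correct),
      accuracy_token = stats::weighted.mean(correct, poly$freq_count),
      confusion = poly |>
        dplyr::mutate(predicted = predicted, correct = correct) |>
        dplyr::count(
          true = .data$stress_position, predicted = .data$predicted,
          wt = NULL, name = "n_type"
        ),
      n = nrow(poly),
      method = method,
      weighting = weighting
    ),
    class = "stress_eval"
  )
}

#' @export
print.stress_eval <- function(x, ...) {
  cat(
    "Stress prediction (", x$method, " method, ", x$weighting,
    "-weighted majorities) on ", x$n, " polysyllables\n",
    sprintf("  type accuracy:  %.4f\n", x$accuracy_type),
    sprintf("  token accuracy: %.4f\n", x$accuracy_token),
    sep = ""
  )
  invisible(x)
}

#' @method tidy stress_eval
#' @export
tidy.stress_eval <- function(x, ...) x$confusion

#' @method glance stress_eval
#' @export
glance.stress_eval <- function(x, ...) {
  tibble::tibble(
    method = x$method, weighting = x$weighting,
    accuracy.type = x$accuracy_type, accuracy.token = x$accuracy_token,
    n = x$n
  )
}

#' Stress-position distribution tables
#'
#' Counts and percentages of types, and per-million token rates, by stress
#' position: overall (monosyllables separated, as they can only be stressed on
#' their sole syllable), by syllabic length, or by part-of-speech category
#' (restricted to nouns, adjectives and verbs, primary tag, polysyllables).
#'
#' @param lexicon A data frame with columns `stress_position`, `n_syll`,
#'   `freq_count` and, for `by = "pos"`, `pos_primary`.
#' @param by `"overall"`, `"length"` or `"pos"`.
#' @param corpus_size Token total for per-million rates; defaults to
#'   `sum(freq_count)`.
#' @return A tibble with grouping columns, `stress` (label), `n_type`,
#'   `pct_type`, `per_million`, `pct_token`. Percentages sum to 100 within each
#'   group (up to rounding of the inputs).
#' @export
stress_distribution <- function(lexicon, by = c("overall", "length", "pos"),
                                corpus_size = NULL) {
  by <- match.arg(by)
  stopifnot(all(c("stress_position", "n_syll", "freq_count") %in% names(lexicon)))
  if (is.null(corpus_size)) corpus_size <- sum(lexicon$freq_count)
  d <- dplyr::filter(lexicon, !is.na(.data$stress_position))
  d$stress <- stress_label(d$stress_position)
  grouping <- switch(by,
    overall = character(),
    length = "n_syll",
    pos = "pos_primary"
  )
  if (by == "pos") {
    stopifnot("pos_primary" %in% names(d))
    d <- dplyr::filter(
      d, .data$pos_primary %in% c("noun", "adjective", "verb"),
      .data$stress_position > 0L
    )
  }
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::count(.data$stress, wt = NULL, name = "n_type") |>
    dplyr::left_join(
      d |>
        dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "stress")))) |>
        dplyr::summarise(n_token = sum(.data$freq_count), .groups = "drop"),
      by = c(grouping, "stress")
    ) |>
    dplyr::mutate(
      pct_type = 100 * .data$n_type / sum(.data$n_type),
      per_million = .data$n_token / corpus_size * 1e6,
      pct_token = 100 * .data$n_token / sum(.data$n_token)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_token")
}
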