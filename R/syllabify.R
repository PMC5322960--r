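# Two syllabifiers:
#  * orthographic: the school-grammar rule — an intervocalic consonant cluster
#    begins a syllable if some Greek word starts with that cluster; otherwise
#    the first letter joins the previous syllable and the remaining consonants
#    begin the next one (applied once, per the grammar's formulation);
#  * phonological: maximal onset over phone sequences — for each intervocalic
#    consonant run, the longest suffix that is a legal cluster under a
#    cluster_rules() set becomes the next onset, the remainder the previous
#    coda. Word-initial runs attach wholly to the first syllable; coda legality
#    is not checked.

#' Construct a syllabification
#'
#' @param units Character vector of syllable strings (letters or phone
#'   symbols); their concatenation must equal the source string.
#' @param stressed 1-based index of the stressed unit, or `NA`.
#' @param type `"orthographic"` or `"phonological"`.
#' @return An object of class `gk_syllables`.
#' @export
syllabification <- function(units, stressed = NA_integer_,
                            type = c("orthographic", "phonological")) {
  type <- match.arg(type)
  stopifnot(is.character(units), length(units) >= 1)
  stressed <- as.integer(stressed)
  if (!is.na(stressed)) stopifnot(stressed >= 1, stressed <= length(units))
  structure(list(units = units, stressed = stressed, type = type),
    class = "gk_syllables"
  )
}

#' @export
format.gk_syllables <- function(x, ...) {
  u <- x$units
  if (!is.na(x$stressed)) u[x$stressed] <- paste0("'", u[x$stressed])
  paste(u, collapse = "-")
}

#' @export
print.gk_syllables <- function(x, ...) {
  cat("<syllables:", x$type, "> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.gk_syllables <- function(x, ...) paste(x$units, collapse = "-")

#' Number of syllables
#' @param x A `gk_syllables` object.
#' @return Integer.
#' @export
n_syllables <- function(x) {
  stopifnot(inherits(x, "gk_syllables"))
  length(x$units)
}

#' Attested word-initial consonant clusters
#'
#' The set of maximal word-initial consonant-letter sequences observed in a
#' word list, stress-stripped and with final sigma mapped to sigma. The
#' inventory is prefix-closed (any prefix of a word-initial cluster also begins
#' some word reading) and always contains the single consonants observed.
#'
#' @param words Character vector of normalized Greek words.
#' @return Character vector of onset clusters (letter strings).
#' @examples
#' build_onset_inventory(c("στρατός", "θρόνος", "πατέρας"))
#' @export
build_onset_inventory <- function(words) {
  stopifnot(is.character(words), length(words) >= 1)
  base <- gk_base_letters(strip_stress(words))
  onsets <- stringr::str_extract(base, paste0(
    "^[", paste(setdiff(gk_consonant_letters, "ς"), collapse = ""), "]+"
  ))
  onsets <- onsets[!is.na(onsets)]
  if (length(onsets) == 0L) {
    return(character(0))
  }
  # prefix closure
  all <- unlist(lapply(onsets, function(o) {
    vapply(seq_len(nchar(o)), function(k) stringr::str_sub(o, 1, k), character(1))
  }))
  sort(unique(all))
}

#' Default onset inventory
#'
#' Word-initial consonant-letter clusters attested in common Modern Greek
#' vocabulary, prefix-closed. Used by [syllabify_orth()] when no corpus-derived
#' inventory is supplied; [build_onset_inventory()] derives one from any word
#' list.
#'
#' @return Character vector of onset clusters.
#' @export
greek_onsets <- function() {
  singles <- setdiff(gk_consonant_letters, "ς")
  doubles <- c(
    "βγ", "βδ", "βλ", "βρ", "γδ", "γκ", "γλ", "γν", "γρ",
    "δρ", "θλ", "θν", "θρ", "κβ", "κλ", "κν", "κρ", "κτ",
    "μν", "μπ", "ντ", "πλ", "πν", "πρ", "πτ",
    "σβ", "σγ", "σθ", "σκ", "σμ", "σπ", "στ", "σφ", "σχ",
    "τζ", "τμ", "τρ", "τσ",
    "φθ", "φλ", "φρ", "φτ",
    "χλ", "χν", "χρ", "χτ"
  )
  triples <- c(
    "γκλ", "γκρ", "μπλ", "μπρ", "ντρ",
    "σκλ", "σκρ", "σπλ", "σπρ", "στρ", "σφρ"
  )
  sort(unique(c(singles, doubles, triples)))
}

#' Orthographic (school-grammar) syllabification
#'
#' One syllable per vowel-grapheme group; an intervocalic consonant cluster is
#' kept whole as the next syllable's onset when it is in the attested-onset
#' inventory, otherwise its first letter closes the previous syllable and the
#' remaining consonants begin the next one. Ambiguous CiV vowel patterns are
#' merged into one syllable or split into two per the supplied policy.
#'
#' @param word A normalized Greek word (single string).
#' @param onsets Attested onset inventory, see [greek_onsets()] and
#'   [build_onset_inventory()].
#' @param civ A [civ_policy()] or per-site decision vector, as in [g2p()].
#' @param iterate Re-test the remainder after stripping the first letter
#'   (recursive variant of the grammar rule). Off by default, matching the
#'   grammar's single-application formulation.
#' @return A `gk_syllables` object (orthographic units).
#' @examples
#' syllabify_orth("θάλασσα")
#' syllabify_orth("άνθρωπος")
#' @export
syllabify_orth <- function(word, onsets = greek_onsets(), civ = default_civ_policy(),
                           iterate = FALSE) {
  stopifnot(is.character(word), length(word) == 1)
  decisions <- gk_civ_decisions(word, civ)
  toks <- gk_tokenize(word, consonant_digraphs = FALSE)
  toks <- gk_apply_civ(toks, decisions)
  v_idx <- which(toks$type == "vowel")
  if (length(v_idx) == 0L) {
    stop("word \"", word, "\" has no vowel nucleus", call. = FALSE)
  }
  n_units <- length(v_idx)
  onset_of <- character(n_units)
  coda_of <- character(n_units)

  run_between <- function(from, to) { # consonant tokens strictly between
    if (to - from <= 1L) {
      return(character(0))
    }
    toks$token[(from + 1L):(to - 1L)]
  }

  onset_of[1] <- paste(toks$token[seq_len(v_idx[1] - 1L)], collapse = "")
  for (u in seq_len(n_units - 1L)) {
    run <- run_between(v_idx[u], v_idx[u + 1L])
    if (length(run) == 0L) {
      next
    }
    key <- gk_base_letters(paste(run, collapse = ""))
    if (key %in% onsets) {
      onset_of[u + 1L] <- paste(run, collapse = "")
    } else if (!iterate) {
      coda_of[u] <- run[1]
      onset_of[u + 1L] <- paste(run[-1], collapse = "")
    } else {
      k <- 1L
      while (k < length(run) &&
        !(gk_base_letters(paste(run[(k + 1L):length(run)], collapse = "")) %in% onsets)) {
        k <- k + 1L
      }
      coda_of[u] <- paste(run[seq_len(k)], collapse = "")
      onset_of[u + 1L] <- paste(run[-seq_len(k)], collapse = "")
    }
  }
  n_tok <- length(toks$token)
  if (v_idx[n_units] < n_tok) {
    coda_of[n_units] <- paste(
      toks$token[(v_idx[n_units] + 1L):n_tok],
      collapse = ""
    )
  }
  units <- paste0(onset_of, toks$token[v_idx], coda_of)
  accented <- which(gk_is_stressed(units))
  stressed <- if (length(accented) == 1L) accented else NA_integer_
  syllabification(units, stressed, type = "orthographic")
}

#' Phonological (maximal-onset) syllabification
#'
#' For each intervocalic consonant run, the longest suffix that is a legal
#' onset cluster under `rules` becomes the next syllable's onset and the
#' remainder the previous syllable's coda. Word-initial runs attach wholly to
#' the first syllable regardless of legality; coda legality is not checked.
#'
#' @param x A `gk_phoneseq` (see [g2p()]).
#' @param rules A [cluster_rules()] object.
#' @return A `gk_syllables` object (phonological units). The phone vectors of
#'   the units are available as attribute `"unit_phones"`.
#' @examples
#' syllabify_phon(g2p("καμβάς"))
#' syllabify_phon(g2p("άρμα"))
#' @export
syllabify_phon <- function(x, rules = default_cluster_rules()) {
  stopifnot(inherits(x, "gk_phoneseq"))
  ph <- x$phones
  v_idx <- which(gk_is_vowel_phone(ph))
  if (length(v_idx) == 0L) {
    stop("phone sequence has no vowel nucleus", call. = FALSE)
  }
  n_units <- length(v_idx)
  onset_of <- vector("list", n_units)
  coda_of <- vector("list", n_units)
  onset_of[[1]] <- ph[seq_len(v_idx[1] - 1L)]
  for (u in seq_len(n_units - 1L)) {
    lo <- v_idx[u] + 1L
    hi <- v_idx[u + 1L] - 1L
    run <- if (hi >= lo) ph[lo:hi] else character(0)
    if (length(run) == 0L) {
      onset_of[[u + 1L]] <- character(0)
      next
    }
    k <- length(run)
    while (k > 1L && !isTRUE(cluster_is_legal_onset(run[(length(run) - k + 1L):length(run)], rules))) {
      k <- k - 1L
    }
    onset_of[[u + 1L]] <- run[(length(run) - k + 1L):length(run)]
    coda_of[[u]] <- run[seq_len(length(run) - k)]
  }
  if (v_idx[n_units] < length(ph)) {
    coda_of[[n_units]] <- ph[(v_idx[n_units] + 1L):length(ph)]
  }
  unit_phones <- lapply(seq_len(n_units), function(u) {
    c(onset_of[[u]] %||% character(0), ph[v_idx[u]], coda_of[[u]] %||% character(0))
  })
  units <- vapply(unit_phones, paste, character(1), collapse = "")
  stressed <- if (is.na(x$stress)) NA_integer_ else which(v_idx == x$stress)
  out <- syllabification(units, stressed, type = "phonological")
  attr(out, "unit_phones") <- unit_phones
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
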