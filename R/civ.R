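# Resolution of ambiguous CiV (consonant + i-vowel + vowel) letter patterns.
# Resolution order: per-word exception lexicon first (mirroring dictionary
# consultation), then the per-cluster majority label, then the policy fallback.

#' CiV disambiguation policy
#'
#' Bundles the three resolution sources for ambiguous CiV sites: a per-word
#' exception lexicon (takes precedence), a per-cluster majority table, and a
#' fallback for clusters covered by neither.
#'
#' The package default ships a curated exception lexicon of common synizesis
#' (one-syllable) words in `inst/extdata/civ_exceptions.tsv` and labels every
#' common i+V cluster as two syllables by majority — the conservative
#' full-vowel reading, which is also the tie rule used by [civ_majority()].
#'
#' @param stats A tibble with columns `cluster` and `majority` (`"one"` or
#'   `"two"`), e.g. the output of [civ_majority()]; or `NULL`.
#' @param exceptions A tibble with columns `word` and `parse` (`"one"`/`"two"`),
#'   or `NULL`.
#' @param fallback What to do for a site whose cluster has neither an exception
#'   nor a majority entry: `"two"`, `"one"`, or `"error"`.
#' @return An object of class `civ_policy`.
#' @seealso [resolve_civ()], [civ_majority()], [civ_sites()]
#' @export
civ_policy <- function(stats = default_civ_stats(),
                       exceptions = default_civ_exceptions(),
                       fallback = c("two", "one", "error")) {
  fallback <- match.arg(fallback)
  if (!is.null(stats)) {
    stopifnot(all(c("cluster", "majority") %in% names(stats)))
    stopifnot(all(stats$majority %in% c("one", "two")))
  }
  if (!is.null(exceptions)) {
    stopifnot(all(c("word", "parse") %in% names(exceptions)))
    stopifnot(all(exceptions$parse %in% c("one", "two")))
  }
  structure(
    list(stats = stats, exceptions = exceptions, fallback = fallback),
    class = "civ_policy"
  )
}

#' Default CiV cluster majority labels
#'
#' Majority parse labels for the common i+V vowel-letter clusters. All default
#' to the two-syllable (full vowel) reading; one-syllable words are carried by
#' the exception lexicon. Counts computed from an actual lexicon via
#' [civ_majority()] can replace this table in [civ_policy()].
#'
#' @return A tibble with columns `cluster` and `majority`.
#' @export
default_civ_stats <- function() {
  clusters <- c(
    "ια", "ιε", "ιο", "ιω", "ιου", "ιαι", "ιει", "ιοι",
    "υα", "υε", "υο", "υω", "υου",
    "ηα", "ηο", "ηω",
    "εια", "ειο", "ειω", "ειου",
    "οια", "οιο", "οιω", "οιου",
    "υια", "υιο"
  )
  tibble::tibble(cluster = clusters, majority = "two")
}

#' Default CiV exception lexicon
#'
#' Curated per-word one-syllable (synizesis) readings that override the cluster
#' majority, shipped as a plain TSV in `inst/extdata/civ_exceptions.tsv`.
#'
#' @return A tibble with columns `word` and `parse`.
#' @export
default_civ_exceptions <- function() {
  if (is.null(.gk_cache$civ_exceptions)) {
    path <- system.file("extdata", "civ_exceptions.tsv", package = "hellex")
    .gk_cache$civ_exceptions <- readr::read_tsv(
      path,
      col_types = readr::cols(.default = readr::col_character())
    )
  }
  .gk_cache$civ_exceptions
}

#' Default CiV policy (cached)
#'
#' The [civ_policy()] built from [default_civ_stats()] and
#' [default_civ_exceptions()], constructed once per session.
#'
#' @return A `civ_policy` object.
#' @export
default_civ_policy <- function() {
  if (is.null(.gk_cache$civ_policy)) .gk_cache$civ_policy <- civ_policy()
  .gk_cache$civ_policy
}

#' Resolve the CiV sites of a word
#'
#' Applies a [civ_policy()] to every ambiguous CiV site of a word: the
#' exception lexicon wins if the word is listed, otherwise the majority label
#' for the site's cluster, otherwise the policy fallback (which may be an
#' error). Each decision is returned with its provenance.
#'
#' @param word A normalized Greek word (single string).
#' @param policy A [civ_policy()] object.
#' @return A tibble with one row per site: `site`, `start`, `cluster`, `parse`
#'   (`"one"` or `"two"`), `source` (`"exception"`, `"majority"`, `"fallback"`).
#' @examples
#' resolve_civ("κυάνιο")
#' @export
resolve_civ <- function(word, policy = default_civ_policy()) {
  stopifnot(inherits(policy, "civ_policy"))
  sites <- gk_civ_sites_tokens(gk_tokenize(word))
  res <- gk_resolve_sites(word, sites, policy)
  tibble::tibble(
    site = sites$site, start = sites$start, cluster = sites$cluster,
    parse = res$parse, source = res$source
  )
}

# shared resolution core over plain site vectors
gk_resolve_sites <- function(word, sites, policy) {
  n <- length(sites$site)
  parse <- character(n)
  source <- character(n)
  if (n == 0L) {
    return(list(parse = parse, source = source))
  }
  exc <- NULL
  if (!is.null(policy$exceptions)) {
    key <- strip_stress(word)
    hit <- policy$exceptions$word == key | policy$exceptions$word == word
    if (any(hit)) exc <- policy$exceptions$parse[which(hit)[1]]
  }
  for (s in seq_len(n)) {
    if (!is.null(exc)) {
      parse[s] <- exc
      source[s] <- "exception"
    } else if (!is.null(policy$stats) && sites$cluster[s] %in% policy$stats$cluster) {
      parse[s] <- policy$stats$majority[match(sites$cluster[s], policy$stats$cluster)]
      source[s] <- "majority"
    } else if (policy$fallback == "error") {
      stop(
        "unresolved CiV site \"", sites$cluster[s], "\" in word \"", word,
        "\": no exception or majority entry", call. = FALSE
      )
    } else {
      parse[s] <- policy$fallback
      source[s] <- "fallback"
    }
  }
  list(parse = parse, source = source)
}

# decisions vector for a word under a policy / explicit character vector
gk_civ_decisions <- function(word, civ) {
  sites <- gk_civ_sites_tokens(gk_tokenize(word))
  n <- length(sites$site)
  if (n == 0L) {
    return(character())
  }
  if (is.null(civ)) {
    stop(
      "word \"", word, "\" has ", n,
      " ambiguous CiV site(s) but no CiV policy or decisions were supplied",
      call. = FALSE
    )
  }
  if (inherits(civ, "civ_policy")) {
    return(gk_resolve_sites(word, sites, civ)$parse)
  }
  stopifnot(is.character(civ), all(civ %in% c("one", "two")))
  if (length(civ) != n) {
    stop(
      "word \"", word, "\" has ", n, " CiV site(s) but ",
      length(civ), " decision(s) were supplied",
      call. = FALSE
    )
  }
  civ
}

#' Majority parse per CiV cluster from a parsed lexicon
#'
#' Counts, for every ambiguous CiV cluster occurring in a lexicon with verified
#' syllabifications, how often the cluster is parsed into one versus two
#' syllables, and labels the majority. Ties resolve to `"two"` (the
#' conservative full-vowel reading).
#'
#' @param lexicon A data frame with columns `word` and `orth_syll`
#'   (hyphen-joined orthographic syllables, e.g. `"κυ-ά-νι-ο"`).
#' @return A tibble with columns `cluster`, `n_one`, `n_two`, `majority`.
#' @examples
#' lex <- tibble::tibble(
#'   word = c("κυάνιο", "γυάλα"),
#'   orth_syll = c("κυ-ά-νι-ο", "γυά-λα")
#' )
#' civ_majority(lex)
#' @export
civ_majority <- function(lexicon) {
  stopifnot(all(c("word", "orth_syll") %in% names(lexicon)))
  rows <- purrr::map2(lexicon$word, lexicon$orth_syll, function(w, syl) {
    sites <- civ_sites(w)
    if (nrow(sites) == 0L) {
      return(NULL)
    }
    # letter index of each unit boundary in the unhyphenated word
    units <- stringr::str_split(syl, "-")[[1]]
    bounds <- cumsum(nchar(units))
    starts <- c(1L, utils::head(bounds, -1) + 1L)
    unit_of <- function(pos) which(pos >= starts & pos <= bounds)[1]
    sites$parse <- vapply(seq_len(nrow(sites)), function(s) {
      i_unit <- unit_of(sites$start[s])
      # the vowel group following the i-group starts right after it unless merged
      i_len <- nchar(sites$cluster[s]) # i-group + following group letters
      v_pos <- sites$start[s] + i_len - 1L # last letter of the pattern
      v_unit <- unit_of(v_pos)
      if (identical(i_unit, v_unit)) "one" else "two"
    }, character(1))
    sites
  })
  parsed <- dplyr::bind_rows(rows)
  if (is.null(parsed) || nrow(parsed) == 0L) {
    return(tibble::tibble(
      cluster = character(), n_one = integer(),
      n_two = integer(), majority = character()
    ))
  }
  parsed |>
    dplyr::count(.data$cluster, .data$parse) |>
    tidyr::pivot_wider(
      names_from = "parse", values_from = "n",
      values_fill = 0L, names_prefix = "n_"
    ) |>
    (\(d) {
      if (!"n_one" %in% names(d)) d$n_one <- 0L
      if (!"n_two" %in% names(d)) d$n_two <- 0L
      d
    })() |>
    dplyr::mutate(majority = ifelse(.data$n_one > .data$n_two, "one", "two")) |>
    dplyr::select("cluster", "n_one", "n_two", "majority") |>
    dplyr::arrange(.data$cluster)
}
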