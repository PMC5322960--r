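# Onset-cluster legality. A two-consonant cluster may begin a syllable when
# the left consonant belongs to a category further left than the right one on
# the Manner-of-Articulation or the Place-of-Articulation scale (at least one
# of the two), subject to a binary voicing criterion that is adequate on its
# own to force a split. The strict rule set additionally treats liquid-initial
# and nasal+liquid clusters as always heterosyllabic and evaluates clusters
# containing nasals/liquids on the ordinary scales; the permissive (IPLR-style)
# preset instead gives such clusters a free pass.

#' Consonant classification scales
#'
#' Ordinal Manner-of-Articulation and Place-of-Articulation classes plus
#' voicing for every consonant phone. MoA runs stop < affricate < fricative <
#' nasal < liquid; PoA runs velar < labial < coronal < palatal. `sonorant`
#' marks nasals and liquids, which are exempt from the obstruent voicing
#' criterion. The table is data, not code: pass an edited copy to
#' [cluster_rules()] to change the legality engine's behaviour.
#'
#' @return A tibble with columns `phone`, `moa`, `poa`, `voiced`, `sonorant`.
#' @export
consonant_profiles <- function() {
  tibble::tribble(
    ~phone, ~moa, ~poa, ~voiced, ~sonorant,
    "p", 1L, 2L, FALSE, FALSE,
    "b", 1L, 2L, TRUE, FALSE,
    "t", 1L, 3L, FALSE, FALSE,
    "d", 1L, 3L, TRUE, FALSE,
    "k", 1L, 1L, FALSE, FALSE,
    "g", 1L, 1L, TRUE, FALSE,
    "c", 1L, 4L, FALSE, FALSE,
    "ts", 2L, 3L, FALSE, FALSE,
    "dz", 2L, 3L, TRUE, FALSE,
    "f", 3L, 2L, FALSE, FALSE,
    "v", 3L, 2L, TRUE, FALSE,
    "θ", 3L, 3L, FALSE, FALSE,
    "δ", 3L, 3L, TRUE, FALSE,
    "s", 3L, 3L, FALSE, FALSE,
    "z", 3L, 3L, TRUE, FALSE,
    "x", 3L, 1L, FALSE, FALSE,
    "γ", 3L, 1L, TRUE, FALSE,
    "ç", 3L, 4L, FALSE, FALSE,
    "ʝ", 3L, 4L, TRUE, FALSE,
    "m", 4L, 2L, TRUE, TRUE,
    "ɱ", 4L, 2L, TRUE, TRUE,
    "n", 4L, 3L, TRUE, TRUE,
    "ɲ", 4L, 4L, TRUE, TRUE,
    "ŋ", 4L, 1L, TRUE, TRUE,
    "l", 5L, 3L, TRUE, TRUE,
    "r", 5L, 3L, TRUE, TRUE,
    "ʎ", 5L, 4L, TRUE, TRUE
  )
}

#' Onset-legality rule set
#'
#' @param profiles Consonant classification table, see [consonant_profiles()].
#' @param whitelist Character vector of clusters (phones pasted together, e.g.
#'   `"ft"`) that are always legal regardless of the scales. Empty by default;
#'   a documented slot for attested-cluster additions.
#' @param strict_nasal_liquid Evaluate clusters containing nasals or liquids on
#'   the MoA and PoA scales like any other cluster (`TRUE`, the strict rule
#'   set). With `FALSE` such clusters get a free pass (permissive, IPLR-style).
#' @param voicing_split Voicing disagreement between two obstruents forces a
#'   split on its own.
#' @param liquid_initial_split Clusters starting with a liquid are always
#'   heterosyllabic.
#' @param nasal_liquid_split Nasal followed by liquid is always heterosyllabic.
#' @return An object of class `cluster_rules`.
#' @seealso [iplr_rules()] for the permissive preset, [cluster_is_legal_onset()]
#' @export
cluster_rules <- function(profiles = consonant_profiles(),
                          whitelist = character(),
                          strict_nasal_liquid = TRUE,
                          voicing_split = TRUE,
                          liquid_initial_split = TRUE,
                          nasal_liquid_split = TRUE) {
  stopifnot(all(c("phone", "moa", "poa", "voiced", "sonorant") %in% names(profiles)))
  stopifnot(!anyDuplicated(profiles$phone))
  structure(
    list(
      profiles = profiles,
      whitelist = whitelist,
      strict_nasal_liquid = strict_nasal_liquid,
      voicing_split = voicing_split,
      liquid_initial_split = liquid_initial_split,
      nasal_liquid_split = nasal_liquid_split
    ),
    class = "cluster_rules"
  )
}

#' Default (strict) rule set, cached
#'
#' The [cluster_rules()] object with all strict flags on, constructed once per
#' session; the default of [syllabify_phon()].
#'
#' @return A `cluster_rules` object.
#' @export
default_cluster_rules <- function() {
  if (is.null(.gk_cache$cluster_rules)) .gk_cache$cluster_rules <- cluster_rules()
  .gk_cache$cluster_rules
}

#' Permissive (IPLR-style) rule preset
#'
#' Scale evaluation with a free pass for clusters containing nasals or liquids,
#' no voicing criterion and no heterosyllabic overrides. Under this preset
#' [mv], [rm] and [rp] are legal onsets; under the strict default they split.
#'
#' @inheritParams cluster_rules
#' @return A `cluster_rules` object.
#' @export
iplr_rules <- function(profiles = consonant_profiles(), whitelist = character()) {
  cluster_rules(
    profiles = profiles, whitelist = whitelist,
    strict_nasal_liquid = FALSE, voicing_split = FALSE,
    liquid_initial_split = FALSE, nasal_liquid_split = FALSE
  )
}

#' Judge whether a consonant cluster may begin a syllable
#'
#' Single consonants are always legal; whitelisted clusters are legal;
#' heterosyllabic override patterns are illegal; otherwise every adjacent pair
#' must place the left consonant strictly further left on the MoA or PoA scale
#' (with the free pass for nasal/liquid pairs when the strict flag is off), and
#' obstruent pairs must agree in voicing when the voicing criterion is active.
#'
#' @param cluster Character vector of consonant phone symbols.
#' @param rules A [cluster_rules()] object.
#' @return `TRUE`/`FALSE` with attribute `reason` naming the criterion that
#'   decided the verdict.
#' @examples
#' cluster_is_legal_onset(c("θ", "r"))
#' cluster_is_legal_onset(c("m", "v"))
#' cluster_is_legal_onset(c("m", "v"), iplr_rules())
#' @export
cluster_is_legal_onset <- function(cluster, rules = default_cluster_rules()) {
  stopifnot(is.character(cluster), length(cluster) >= 1)
  prof <- rules$profiles
  missing <- setdiff(cluster, prof$phone)
  if (length(missing) > 0) {
    stop(
      "no consonant profile for phone(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  verdict <- function(value, reason) structure(value, reason = reason)
  if (length(cluster) == 1L) {
    return(verdict(TRUE, "single consonant"))
  }
  if (paste(cluster, collapse = "") %in% rules$whitelist) {
    return(verdict(TRUE, "whitelisted cluster"))
  }
  idx <- match(cluster, prof$phone)
  moa <- prof$moa[idx]
  poa <- prof$poa[idx]
  voiced <- prof$voiced[idx]
  sonorant <- prof$sonorant[idx]
  liquid <- moa == 5L
  nasal <- moa == 4L
  if (rules$liquid_initial_split && liquid[1]) {
    return(verdict(FALSE, "liquid-initial clusters are heterosyllabic"))
  }
  if (rules$nasal_liquid_split &&
    any(nasal[-length(cluster)] & liquid[-1])) {
    return(verdict(FALSE, "nasal+liquid clusters are heterosyllabic"))
  }
  for (i in seq_len(length(cluster) - 1L)) {
    pair <- paste0(cluster[i], cluster[i + 1])
    if (!rules$strict_nasal_liquid && (sonorant[i] || sonorant[i + 1])) {
      next # permissive free pass for nasal/liquid members
    }
    scale_ok <- moa[i] < moa[i + 1] || poa[i] < poa[i + 1]
    if (!scale_ok) {
      return(verdict(FALSE, paste0("[", pair, "] fails both MoA and PoA scales")))
    }
    if (rules$voicing_split && !sonorant[i] && !sonorant[i + 1] &&
      voiced[i] != voiced[i + 1]) {
      return(verdict(FALSE, paste0("[", pair, "] obstruent voicing disagreement")))
    }
  }
  verdict(TRUE, "passes MoA/PoA and voicing criteria")
}
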