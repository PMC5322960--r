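---
title: "Methods: building annotated Greek lexicons with hellex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building annotated Greek lexicons with hellex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hellex)
library(dplyr)
```

hellex turns a Modern Greek word–frequency list into a fully annotated
psycholinguistic lexicon: phonetic transcriptions, two kinds of syllabification,
stress position and stress-predictability measures, orthographic and
phonological similarity metrics, and Zipf-scale frequencies. This vignette
explains the linguistic models behind each stage, the tunable parameters and
their defaults, the synthetic-lexicon generator used for testing, and the
numerical choices and limitations a careful user should know about.

## Text model

All processing assumes lowercase monotonic Greek in composed (NFC) Unicode, so
an accented vowel is one code point and letter indices match letter counts.
`normalize_greek()` enforces this: it composes decomposed input, trims
whitespace, lowercases uppercase input with a warning (uppercase Greek does not
mark the stress diacritic, so information may already be lost upstream), and
rejects non-Greek characters naming the offender. A well-formed word carries at
most one tonos; `strip_stress()` removes it (retaining dialytika, as in ΐ → ϊ)
and is idempotent and length-preserving. The word-final sigma allograph ς is
treated as identical to σ in every rule lookup and similarity metric but is
preserved on output: neighbourhood metrics must not treat a word-final
allograph as a different letter.

Words with dialytika-plus-tonos vowels (ΐ, ΰ) count as stressed. Vowels with
dialytika alone are treated as distinct letters in the metrics; this is an
assumption (reasonable alternatives exist) and is stated here because corpus
counts change slightly under the alternative.

## Grapheme-to-phoneme transcription

Greek orthography is nearly consistent from print to sound, so `g2p()` is a
rule engine, not a trained model. The whole mapping lives in one ordered rule
table (documented at the top of `R/transcribe.R`): longest-grapheme-first
tokenization (vowel digraphs αι ει οι υι ου, the semivowel digraphs αυ ευ ηυ,
consonant digraphs μπ ντ γκ γγ τσ τζ), velar palatalization before front
vowels (κ→c, γ→ʝ, χ→ç), σ-voicing before voiced consonants, [av/af]-type
realization of αυ/ευ, and degemination (Greek has no phonetic geminates).
Word-initial μπ/ντ/γκ are plain voiced stops; word-medially they are
nasal+stop sequences which `simplify_nasals()` reduces ([mb]→[b], [nd]→[d],
[ŋg]→[g]) unless `keep_nasals = TRUE` preserves the allophonic forms.

Phone symbols default to the style common in Greek psycholinguistic resources
(δ, γ, θ, ε); `as_ipa()` maps to standard IPA (ð, ɣ, e). The stress marker
sits on the stressed vowel phone, and `comparison_normalize()` applies the
three adjustments used when comparing transcriptions across databases:
monosyllables lose the redundant stress mark, nasal simplification, and the
labiodental nasal read as [m].

### Ambiguous CiV patterns

The one real ambiguity is the CiV pattern: consonant + i-sounding vowel
grapheme + vowel, where the i is either a full vowel (two syllables, κυάνιο
[ci-'a-ni-o]) or a glide/palatalisation trigger (one syllable, γυάλα
['ʝa-la]). `civ_sites()` finds the sites; a `civ_policy()` resolves them with
three layers: a per-word exception lexicon (the analogue of consulting a
syllabified dictionary) wins; otherwise the per-cluster majority label;
otherwise a fallback. The shipped default labels every common cluster as two
syllables — the conservative full-vowel reading, which is also the tie rule of
`civ_majority()` — and carries the common synizesis words in a curated
exception file (`inst/extdata/civ_exceptions.tsv`). `civ_majority()` computes
real majority tables from any lexicon with verified parses, so a corpus-derived
policy can replace the default. When the one-syllable reading applies, a
preceding [n]/[l] palatalises to [ɲ]/[ʎ], velars to [c]/[ʝ]/[ç], and other
consonants take a following [ç] (voiceless) or [ʝ] (voiced), as in κλεψιά
[kle-'psça]. We follow this prose rule uniformly; palatalisation's theoretical
relationship to syllable structure is left open on purpose.

## Two syllabifiers

**Orthographic (school grammar).** `syllabify_orth()` implements the rule
taught for end-of-line hyphenation: an intervocalic consonant cluster begins a
syllable if some Greek word starts with that cluster; otherwise the first
letter closes the previous syllable and the remaining consonants open the next
one. The attested-onset inventory is data: `greek_onsets()` ships a
prefix-closed inventory from common vocabulary, and `build_onset_inventory()`
derives one from any word list (prefix closure because any prefix of an
attested initial cluster also begins a word reading; it keeps the rule
monotone). The grammar rule is applied once, not recursively, matching its
usual formulation; a recursive variant sits behind `iterate = TRUE` as a
documented extension.

**Phonological (maximal onset).** `syllabify_phon()` assigns each intervocalic
consonant run's longest legal suffix to the following onset and the remainder
to the preceding coda. Legality is scale-based and entirely data-driven
(`consonant_profiles()`): a pair may begin a syllable when the left consonant
is strictly further left on the Manner-of-Articulation scale
(stop < affricate < fricative < nasal < liquid) or the Place-of-Articulation
scale (velar < labial < coronal < palatal), with a binary voicing criterion
that splits disagreeing obstruent pairs on its own. The strict default also
treats liquid-initial and nasal+liquid clusters as always heterosyllabic, so
[mv] (καμβάς [kam-'vas]), [rm] (άρμα ['ar-ma]) and [rp] split. The permissive
preset `iplr_rules()` instead gives clusters containing nasals or liquids a
free pass and drops the voicing criterion and the overrides, which flips
exactly those verdicts — the two rule sets reproduce the two syllabification
traditions for the same words. Word-initial runs attach wholly to the first
syllable regardless of legality, and coda legality is deliberately not
checked: for runs of three or more consonants the rightmost-maximal-legal
suffix wins and the coda is whatever remains.

The profile table is shipped as data rather than hard-coded because the
category memberships are an empirical commitment: users can pass an edited
copy to `cluster_rules()`. Voicing is applied to obstruent pairs only —
sonorants do not contrast in voicing, and applying the criterion to them would
wrongly split obstruent+liquid onsets like [θr] that Greek plainly allows. The
Botinis-style whitelist of always-legal clusters is shipped empty as a
documented slot.

## Stress

Positions are counted from the word end: 1 final, 2 pre-final, 3
antepenultimate; monosyllables are coded 0 and never contribute to prediction.
For tonos-marked Greek the value is always within the final three syllables.

Two prediction procedures are implemented. The *ending-majority* procedure
groups polysyllables by their Colombo ending — the stretch from the pre-final
syllable's nucleus vowel to the last letter, stress-stripped (for glide-merged
syllables the nucleus is the realized vowel, not the glide) — and assigns each
word its group's modal position. The *rime-hierarchy* procedure scans a word's
suffixes from longest to shortest and uses the modal position of the first
suffix attested as a rime (the stretch from the stressed vowel to the last
letter). Majorities can be driven by type counts or token frequency mass; ties
break deterministically pre-final > antepenultimate > final, the corpus-global
frequency order (configurable). `evaluate_stress_prediction()` builds the
index from the same lexicon it scores, with the target included in its own
group; a predicted position deeper than the word's syllable count counts as
incorrect, not skipped. Token weighting uses raw frequency counts, not
per-million rates, so results are invariant to corpus-size normalization.

## Similarity and frequency metrics

* `coltheart_n()`: entries of equal length at Hamming distance exactly one,
  self excluded.
* `old20()`: mean Levenshtein distance (via `utils::adist`, unit costs) to the
  20 closest other entries; applied to transcription strings it serves as
  PLD20. Fewer than 20 candidates is an error, not a silent partial mean —
  silent degradation corrupts corpus statistics.
* Every metric has stressed and unstressed variants: callers pass
  tonos-bearing or `strip_stress()`ed strings (the built lexicon carries both
  columns). The stressed phonological variant keeps the stress marker in the
  string, playing the role the tonos plays orthographically.
* `zipf()`: `log10((count + 1) / (corpus_millions + types_millions)) + 3`,
  i.e. the base-10 log of the Laplace-smoothed frequency per million plus 3;
  the defaults (46.89 million tokens, 0.0353 million types) describe the
  corpus the package's frequency conventions are modelled on, and a value of
  3 always marks one occurrence per million.
* `fleiss_kappa()`: the multi-rater chance-corrected agreement statistic, with
  the large-sample z test; the degenerate single-category case (chance
  agreement 1) is reported as undefined rather than forced to a number.
* `syllable_frequencies()`: type and token counts with per-million rates over
  all syllable slots, stressed and stress-stripped, for either unit type;
  `mean_syllable_frequency()` gives the per-entry means.

## The build pipeline

`build_lexicon()` composes the stages in order: normalize → orthographic
syllabification with CiV disambiguation → transcription → nasal simplification
→ phonological syllabification → stress position → rime and Colombo ending →
frequency measures → neighbourhood metrics → optional PoS tags from a
dictionary cross-check (`pos_annotate()`: the dictionary's first category is
the primary tag, the rest become secondary tags, unmatched words are tagged
`unknown`). Per-word failures are trapped into an `error` column — one bad word
never aborts a corpus build — and corpus-level metrics are computed over the
well-formed rows. The output is an ordinary tibble; `write_lexicon()` writes
TSV (primary) or CSV, in UTF-8 or a reversible ASCII transliteration (one
Latin letter per Greek letter, apostrophe for the tonos, double quote for
dialytika) for environments without Greek text support.

## The synthetic-lexicon generator

`simulate_lexicon()` exists so that every statistical claim in the package can
be tested without any external download. It emulates the distributional
structure of the Greek lexicon as reported in the psycholinguistic literature,
and its defaults are the package's study conditions, chosen once:

* syllable-length distribution of lemma types over lengths 1–7
  (0.8%, 10.4%, 23.8%, 30.2%, 22.2%, 9.3%, 2.6%, renormalised);
* token mass allocated to length classes following the token-by-length
  distribution (monosyllables ≈ 53.5% of tokens despite ≈ 0.8% of types),
  with a Zipf rank-frequency law (exponent 1) within each class;
* PoS mixture noun 58.5%, adjective 25.8%, verb 14.2%, adverb 1.5%, with
  category-specific stress profiles in which adjectives disfavour the
  pre-final position;
* per-length stress-position preferences that make pre-final stress dominant
  for disyllables and antepenultimate stress dominant for lengths ≥ 4;
* an ending inventory (default 60 endings) with planted consistency θ: each
  polysyllable draws an ending and takes its modal stress position with
  probability θ (default 0.9), otherwise one of the other positions its length
  licenses, uniformly.

Words are composed from attested syllable parts — onsets legal under both
syllabifiers, open syllables word-internally, optional word-final ς/ν — so the
gold syllabification, transcription and stress exist by construction and the
parsers are tested against them as a round-trip oracle. The generator records
its own gold transcription from an independent minimal letter–phone map rather
than calling the package's engine.

What the generator does *not* emulate: real Greek morphology (the "words" are
phonotactically plausible nonwords), CiV sites (vowel-adjacent syllables are
avoided by construction so gold parses stay unambiguous), internal codas,
consonant-digraph onsets, and any correlation between frequency and stress
position. Passing tests on synthetic data therefore demonstrate that the
algorithms implement their definitions and recover planted structure — not
that any particular accuracy will be observed on the real lexicon, where the
published tables are the reference.

Problem sizes used by the test suite and the acceptance script — 10,000-word
lexicons for property and recovery checks, 2,500-word builds for the
similarity metrics, 200 random small lexicons for oracle equivalence — were
chosen as the points where the checked statistics are stable.

## Numerical and design choices

* Stress-prediction ties break pre-final > antepenultimate > final;
  CiV majority ties resolve to two syllables. Both are configurable.
* The token-accuracy recovery check uses the binomial 99% confidence interval
  with the design-effect-corrected effective sample size (Σw)²/Σw²: under
  Zipf-distributed weights the nominal n vastly overstates the precision of a
  frequency-weighted proportion.
* `stressed_vowel_index()` is 1-based, as is idiomatic in R.
* OLD20 ties at the cutoff do not change the mean (distances, not identities,
  are averaged), so no tie rule is needed beyond sorting by distance.
* The uppercase (diacritic-free) lexicon variant is not produced: stressed and
  unstressed columns of the lowercase build carry that information.

## Limitations

* The G2P rules cover standard Modern Greek orthography; loanwords with
  exceptional pronunciations and polytonic (ancient/katharevousa) text are out
  of scope, as is cross-word sandhi.
* The default CiV policy is intentionally conservative; without a
  corpus-derived majority table or a larger exception lexicon, genuinely
  ambiguous words default to the two-syllable reading.
* The onset-legality engine is only as good as its profile table; users with
  different theoretical commitments should edit the table, not the code.
* PoS annotation is a dictionary cross-check, not contextual tagging; lemmas
  with several readings receive a primary tag plus secondary tags and genuinely
  ambiguous entries remain ambiguous.
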