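test_that("Zipf values follow the smoothed per-million formula", {
  # 1000 per million -> log10(1000) + 3 = 6
  expect_equal(zipf(999, corpus_millions = 1, types_millions = 1e-9), 6, tolerance = 1e-8)
  # zero counts stay defined (Laplace smoothing)
  expect_equal(zipf(0), 3 - log10(46.9253), tolerance = 1e-12)
  # frequency-per-million of 1 sits at the scale midpoint 3 for any params
  expect_equal(zipf(46.9253 - 1), 3, tolerance = 1e-12)
  expect_equal(zipf(12.5 - 1, corpus_millions = 12, types_millions = 0.5), 3)
  # strictly increasing
  expect_true(all(diff(zipf(0:50)) > 0))
  expect_error(zipf(-1), "negative")
})

test_that("levenshtein matches the DP oracle and the metric axioms", {
  expect_identical(levenshtein("γερος", "γερος"), 0L)
  expect_identical(levenshtein("αρμα", "αρπα"), 1L)
  expect_identical(levenshtein("καμβας", "καβας"), 1L)

  set.seed(11)
  w <- random_greek_strings(30)
  for (i in 1:25) {
    a <- sample(w, 1)
    b <- sample(w, 1)
    c_ <- sample(w, 1)
    expect_identical(levenshtein(a, b), as.integer(oracle_levenshtein(a, b)))
    expect_identical(levenshtein(a, b), levenshtein(b, a)) # symmetry
    expect_identical(levenshtein(a, a), 0L)
    expect_lte(levenshtein(a, c_), levenshtein(a, b) + levenshtein(b, c_))
  }
})

test_that("Coltheart's N counts Hamming-1 neighbours of equal length", {
  expect_identical(coltheart_n("abc", c("abd", "xbc", "abcd")), 2L)
  expect_identical(coltheart_n("αβγ", c("δζη")), 0L)
  expect_identical(coltheart_n("αβγ", c("αβγ")), 0L) # self excluded
  # final sigma is the same letter as sigma
  expect_identical(coltheart_n("γερος", c("γεροσ")), 0L)
  expect_identical(coltheart_n("γερος", c("μεροσ")), 1L)

  set.seed(12)
  lex <- random_greek_strings(60, 3, 5)
  for (w in sample(lex, 20)) {
    expect_identical(coltheart_n(w, lex), oracle_coltheart(w, lex))
  }
})

test_that("OLD20 equals the brute-force oracle", {
  lex <- paste0("αβ", strsplit("γδεζηθικλμνξοπρστυφχψ", "")[[1]]) # 21 distance-1 words
  expect_equal(old20("αβω", lex), 1)
  expect_error(old20("αβω", lex[1:15]), "insufficient lexicon")

  set.seed(13)
  for (rep in 1:8) {
    lex <- unique(random_greek_strings(25, 3, 7))
    w <- sample(lex, 1)
    expect_equal(old20(w, lex), oracle_old20(w, lex), tolerance = 1e-12)
  }
})

test_that("rime runs from the stressed vowel to the end, stress-stripped", {
  expect_identical(rime("γέρος"), "ερος")
  expect_identical(rime("καμβάς"), "ας")
  expect_identical(rime("φώς"), "ως") # degenerate stressed monosyllable
  expect_error(rime("γερος"), "missing stress")
})

test_that("the Colombo ending starts at the pre-final nucleus vowel", {
  expect_identical(colombo_ending("γέρος"), "ερος")
  expect_identical(colombo_ending("γυάλα"), "αλα") # glide is not the nucleus
  expect_identical(colombo_ending("θάλασσα"), "ασσα")
  expect_identical(colombo_ending("πατέρας"), "ερας")
  expect_error(colombo_ending("φως"), "monosyllabic")
})

test_that("stress neighbourhood proportions count types and tokens", {
  lex <- tibble::tibble(
    word = c("a1", "a2", "a3", "a4", "b1"),
    ending = c("αλα", "αλα", "αλα", "αλα", "ιο"),
    stress_position = c(2L, 2L, 2L, 3L, 1L),
    freq_count = c(10, 10, 10, 30, 5)
  )
  g <- stress_neighbourhood(lex)
  expect_equal(g$prop_type[g$ending == "αλα" & g$stress_position == 2], 0.75)
  expect_equal(g$prop_type[g$ending == "αλα" & g$stress_position == 3], 0.25)
  expect_equal(g$prop_token[g$ending == "αλα" & g$stress_position == 2], 0.5)
  expect_equal(g$prop_token[g$ending == "αλα" & g$stress_position == 3], 0.5)
  expect_equal(g$prop_type[g$ending == "ιο"], 1)

  # proportions sum to 1 within groups; annotated proportions in (0, 1]
  sums <- tapply(g$prop_type, g$ending, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  ann <- annotate_stress_neighbourhood(lex)
  expect_true(all(ann$stress_nbhd_type_prop > 0 & ann$stress_nbhd_type_prop <= 1))
  expect_equal(oracle_stress_props(lex)$prop_type, g$prop_type)
})

test_that("rime neighbourhood counts matching rime and position, self excluded", {
  lex <- tibble::tibble(
    rime = c("ας", "ας", "ας", "ος", NA),
    stress_position = c(1L, 1L, 2L, 1L, 1L)
  )
  expect_identical(rime_neighbourhood(lex), c(1L, 1L, 0L, 0L, NA_integer_))
  set.seed(14)
  lex2 <- tibble::tibble(
    rime = sample(c("ας", "ος", "ι"), 40, replace = TRUE),
    stress_position = sample(1:3, 40, replace = TRUE)
  )
  expect_identical(rime_neighbourhood(lex2), oracle_rime_neighbourhood(lex2))
})

test_that("syllable frequency tables count types, tokens and rates", {
  lex <- tibble::tibble(
    word = c("πατέρας", "πατάτα"),
    orth_syll = c("πα-τέ-ρας", "πα-τά-τα"),
    freq_count = c(2, 3)
  )
  tab <- syllable_frequencies(lex, unit = "orth", stressed = TRUE)
  expect_identical(tab$n_type[tab$syllable == "πα"], 2L)
  expect_identical(tab$n_token[tab$syllable == "πα"], 5)
  expect_identical(tab$n_type[tab$syllable == "τέ"], 1L)
  expect_equal(tab$per_million[tab$syllable == "πα"], 1e6)

  # stripped variant merges only tonos-distinguished syllables
  tab_u <- syllable_frequencies(lex, unit = "orth", stressed = FALSE)
  expect_false("τέ" %in% tab_u$syllable)
  expect_identical(tab_u$n_type[tab_u$syllable == "τε"], 1L)
  expect_identical(tab_u$n_type[tab_u$syllable == "πα"], 2L)

  m <- mean_syllable_frequency(lex, tab, unit = "orth", weighting = "type")
  expect_equal(m, c(mean(c(2, 1, 1)), mean(c(2, 1, 1))))
})

test_that("Fleiss' kappa matches hand computation and the pairwise oracle", {
  perfect <- rbind(c(3, 0), c(0, 3), c(3, 0))
  expect_equal(fleiss_kappa(perfect)$kappa, 1)

  # 2 items, 2 raters, complete disagreement: P_bar = 0, P_e = 0.5, kappa = -1
  disagree <- rbind(c(1, 1), c(1, 1))
  expect_equal(fleiss_kappa(disagree)$kappa, -1)

  set.seed(15)
  for (rep in 1:10) {
    m <- t(stats::rmultinom(12, size = 4, prob = c(0.5, 0.3, 0.2)))
    expect_equal(fleiss_kappa(m)$kappa, oracle_fleiss(m), tolerance = 1e-12)
  }

  # random uniform ratings -> kappa near 0 (Monte Carlo)
  set.seed(16)
  big <- t(stats::rmultinom(4000, size = 3, prob = rep(1 / 3, 3)))
  expect_lt(abs(fleiss_kappa(big)$kappa), 0.03)

  expect_error(fleiss_kappa(rbind(c(2, 0), c(1, 1), c(3, 0))), "same number of raters")
  expect_true(is.na(fleiss_kappa(rbind(c(3, 0), c(3, 0)))$kappa)) # P_e = 1

  g <- glance(fleiss_kappa(perfect))
  expect_identical(g$n.raters, 3L)
})
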