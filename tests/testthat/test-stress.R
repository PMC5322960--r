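test_that("stress position is counted from the word end", {
  expect_identical(stress_position(syllabify_phon(g2p("καμβάς"))), 1L) # final
  expect_identical(stress_position(syllabify_phon(g2p("γυάλα"))), 2L) # pre-final
  expect_identical(stress_position(syllabify_phon(g2p("άνθρωπος"))), 3L) # antepenult
  expect_identical(stress_position(syllabify_orth("φως")), 0L) # monosyllable
  expect_error(stress_position(syllabify_orth("γερος")), "missing stress")
  expect_identical(
    as.character(stress_label(c(0L, 1L, 2L, 3L, 4L))),
    c("monosyllable", "final", "pre-final", "antepenultimate", "earlier")
  )
})

test_that("ending-majority prediction picks the group mode with the tie-break", {
  idx <- tibble::tibble(
    ending = c("αλα", "αλα", "ικο", "ος", "ος"),
    stress_position = c(2L, 3L, 1L, 1L, 3L),
    n_type = c(3L, 1L, 1L, 2L, 2L),
    n_token = c(10, 90, 5, 1, 1)
  )
  expect_identical(predict_stress_ending("αλα", idx), 2L) # 75% pre-final
  expect_identical(predict_stress_ending("ικο", idx), 1L) # singleton group
  expect_identical(predict_stress_ending("ος", idx), 3L) # tie: 3 beats 1
  expect_identical(predict_stress_ending("αλα", idx, weighting = "token"), 3L)
  expect_identical(predict_stress_ending("ζζζ", idx), NA_integer_) # no prediction
})

test_that("rime-hierarchy prediction takes the longest attested suffix", {
  idx <- tibble::tibble(
    rime = c("ερος", "ος"),
    stress_position = c(2L, 1L),
    n_type = c(5L, 50L),
    n_token = c(5, 50)
  )
  # 4-letter suffix attested: shorter suffixes ignored
  expect_identical(predict_stress_rime("ξεθερος", idx), 2L)
  # only the short suffix attested
  expect_identical(predict_stress_rime("ξαλος", idx), 1L)
  expect_identical(predict_stress_rime("ξαλι", idx), NA_integer_)
  empty <- idx[0, ]
  expect_identical(predict_stress_rime("ξεθερος", empty), NA_integer_)
})

test_that("evaluation matches a brute-force hand computation", {
  # 8 polysyllables over two endings + 1 monosyllable
  lex <- tibble::tibble(
    word = c("βάλα", "κάλα", "σαλά", "μάλα", "πύρος", "ξηρός", "θηρός", "μηρός", "φως"),
    ending = c("αλα", "αλα", "αλα", "αλα", "ηρος", "ηρος", "ηρος", "ηρος", NA),
    rime = c("αλα", "αλα", "α", "αλα", "υρος", "ος", "ος", "ος", NA),
    stress_position = c(2L, 2L, 1L, 2L, 2L, 1L, 1L, 1L, 0L),
    n_syll = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 1L),
    freq_count = c(1, 1, 6, 1, 2, 1, 1, 1, 100)
  )
  ev <- evaluate_stress_prediction(lex, method = "ending", weighting = "type")
  # ending αλα mode = 2 (3 of 4), ηρος mode = 1 (3 of 4): correct 3 + 3 of 8
  expect_equal(ev$accuracy_type, 6 / 8)
  expect_equal(ev$accuracy_token, (1 + 1 + 1 + 1 + 1 + 1) / 14)
  expect_identical(ev$n, 8L)

  # token weighting flips the αλα mode to final (6 vs 3)
  ev_tok <- evaluate_stress_prediction(lex, method = "ending", weighting = "token")
  expect_equal(ev_tok$accuracy_type, (1 + 3) / 8)

  # rime method: each word's own rime is attested, hierarchy from the longest
  ev_r <- evaluate_stress_prediction(lex, method = "rime", weighting = "type")
  # rimes: αλα(mode 2, 3 types), α(1), υρος(2), ος(1): predictions
  # βάλα..μάλα -> 2 correct(3); σαλά: suffix αλά->stripped αλα attested -> 2, true 1 wrong;
  # πύρος -> υρος -> 2 correct; ξηρός/θηρός/μηρός -> ηρος not attested, ος -> 1 correct(3)
  expect_equal(ev_r$accuracy_type, 7 / 8)

  g <- glance(ev)
  expect_identical(g$method, "ending")
  expect_s3_class(tidy(ev), "tbl_df")
})

test_that("monosyllables never contribute and empty input errors", {
  mono <- tibble::tibble(
    word = "φως", ending = NA, rime = NA,
    stress_position = 0L, n_syll = 1L, freq_count = 5
  )
  expect_error(evaluate_stress_prediction(mono), "no polysyllabic")
})

test_that("a predicted position deeper than the word counts as incorrect", {
  lex <- tibble::tibble(
    word = c("βαθέκατο", "μεσέκατο", "λεπτή"),
    ending = c("εκατο", "εκατο", "εκατο"),
    rime = c("εκατο", "εκατο", "η"),
    stress_position = c(3L, 3L, 1L),
    n_syll = c(4L, 4L, 2L),
    freq_count = c(1, 1, 1)
  )
  ev <- evaluate_stress_prediction(lex, method = "ending")
  # mode of εκατο = 3; λεπτή (2 syllables) predicted 3 > n_syll -> incorrect
  expect_equal(ev$accuracy_type, 2 / 3)
})

test_that("distribution tables tally counts and percentages", {
  lex <- tibble::tibble(
    word = paste0("w", 1:10),
    stress_position = c(0L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 2L, 3L),
    n_syll = c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 5L),
    freq_count = c(100, 10, 10, 20, 5, 5, 10, 20, 10, 10),
    pos_primary = c(
      "noun", "noun", "verb", "adjective", "noun",
      "noun", "adjective", "noun", "verb", "unknown"
    )
  )
  overall <- stress_distribution(lex)
  expect_equal(sum(overall$pct_type), 100)
  expect_equal(sum(overall$pct_token), 100)
  expect_identical(
    overall$n_type[overall$stress == "monosyllable"], 1L
  )
  expect_identical(overall$n_type[overall$stress == "pre-final"], 4L)
  expect_equal(
    overall$per_million[overall$stress == "monosyllable"],
    100 / 200 * 1e6
  )

  by_len <- stress_distribution(lex, by = "length")
  expect_equal(
    by_len$pct_type[by_len$n_syll == 2 & by_len$stress == "final"], 200 / 3
  )
  sums <- tapply(by_len$pct_type, by_len$n_syll, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  by_pos <- stress_distribution(lex, by = "pos")
  expect_setequal(unique(by_pos$pos_primary), c("noun", "verb", "adjective"))
  expect_false(any(by_pos$stress == "monosyllable"))

  one <- stress_distribution(tibble::tibble(
    word = "a", stress_position = 2L, n_syll = 3L, freq_count = 1
  ))
  expect_equal(one$pct_type, 100)
})

test_that("single trisyllabic penult word gives one 100% pre-final row", {
  one <- stress_distribution(tibble::tibble(
    word = "πατέρας", stress_position = 2L, n_syll = 3L, freq_count = 2
  ))
  expect_identical(nrow(one), 1L)
  expect_identical(as.character(one$stress), "pre-final")
  expect_equal(one$pct_type, 100)
})
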