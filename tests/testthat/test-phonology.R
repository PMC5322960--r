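expect_phones <- function(word, phones, stress, ...) {
  ps <- g2p(word, ...)
  expect_identical(ps$phones, phones, label = paste("phones of", word))
  expect_identical(ps$stress, as.integer(stress), label = paste("stress of", word))
}

test_that("transcription reproduces the worked examples", {
  expect_phones("νιώθω", c("ɲ", "o", "θ", "o"), 2)
  expect_phones("γυάλα", c("ʝ", "a", "l", "a"), 2)
  expect_phones("κυάνιο", c("c", "i", "a", "n", "i", "o"), 3)
  expect_phones("αντένα", c("a", "d", "ε", "n", "a"), 3)
  expect_phones("διαβάτης", c("δ", "ʝ", "a", "v", "a", "t", "i", "s"), 5)
  expect_phones("κλεψιά", c("k", "l", "ε", "p", "s", "ç", "a"), 7)
  expect_phones("ελέγκτρια", c("ε", "l", "ε", "g", "t", "r", "i", "a"), 3)
  expect_phones("καμβάς", c("k", "a", "m", "v", "a", "s"), 5)
})

test_that("core context rules fire", {
  # velar palatalization before front vowels
  expect_phones("γέρος", c("ʝ", "ε", "r", "o", "s"), 2)
  expect_phones("κήπος", c("c", "i", "p", "o", "s"), 2)
  expect_phones("χέρι", c("ç", "ε", "r", "i"), 2)
  # σ voices before voiced consonants
  expect_phones("κόσμος", c("k", "o", "z", "m", "o", "s"), 2)
  # αυ/ευ as [av]/[ef] by following voicing
  expect_phones("αύριο", c("a", "v", "r", "i", "o"), 1)
  expect_phones("ευχαριστώ", c("ε", "f", "x", "a", "r", "i", "s", "t", "o"), 9)
  # word-initial voiced-stop digraphs are plain stops
  expect_phones("μπαμπάς", c("b", "a", "b", "a", "s"), 4)
  expect_phones("ντομάτα", c("d", "o", "m", "a", "t", "a"), 4)
})

test_that("keep_nasals preserves medial nasal+stop allophones", {
  ps <- g2p("αντένα", keep_nasals = TRUE)
  expect_identical(ps$phones, c("a", "n", "d", "ε", "n", "a"))
  expect_identical(g2p("αντένα")$phones, c("a", "d", "ε", "n", "a"))
})

test_that("nasal simplification drops nasals before homorganic stops only", {
  akumbao <- phone_seq(c("a", "k", "u", "m", "b", "a", "o"), stress = 6)
  expect_identical(
    simplify_nasals(akumbao)$phones,
    c("a", "k", "u", "b", "a", "o")
  )
  expect_identical(simplify_nasals(akumbao)$stress, 5L)

  elenktria <- phone_seq(c("ε", "l", "ε", "ŋ", "g", "t", "r", "i", "a"), stress = 3)
  expect_identical(format(simplify_nasals(elenktria)), "εl'εgtria")

  kamvas <- phone_seq(c("k", "a", "m", "v", "a", "s"), stress = 5)
  expect_identical(simplify_nasals(kamvas)$phones, kamvas$phones)

  # idempotence
  for (ps in list(akumbao, elenktria, kamvas)) {
    once <- simplify_nasals(ps)
    expect_identical(simplify_nasals(once), once)
  }
})

test_that("comparison normalization destresses monosyllables", {
  min_seq <- phone_seq(c("m", "i", "n"), stress = 2)
  out <- comparison_normalize(min_seq)
  expect_true(is.na(out$stress))
  expect_identical(out$phones, c("m", "i", "n"))

  # polysyllables keep their stress; labiodental nasal collapses to [m]
  poly <- phone_seq(c("a", "ɱ", "v", "a"), stress = 4)
  out2 <- comparison_normalize(poly)
  expect_identical(out2$phones, c("a", "m", "v", "a"))
  expect_identical(out2$stress, 4L)
  expect_identical(comparison_normalize(out2), out2)
})

test_that("transcription is deterministic and stress-neutral on CiV-free words", {
  words <- c("γέρος", "θάλασσα", "πατέρας", "άνθρωπος", "κόσμος", "ελέγκτρια")
  for (w in words) {
    a <- g2p(w)
    b <- g2p(w)
    expect_identical(a, b)
    u <- g2p(strip_stress(w))
    expect_identical(u$phones, a$phones, label = paste("stress-neutrality", w))
    expect_true(is.na(u$stress))
  }
})

test_that("malformed input is rejected with position information", {
  expect_error(g2p("γqρος"), "unmappable grapheme")
  expect_error(g2p("βγγρ"), "no vowel nucleus")
  expect_error(phone_seq(c("a", "Q")), "outside the inventory")
  expect_error(phone_seq(c("a", "p"), stress = 2), "vowel phone")
})

test_that("IPA export maps the paper-style symbols", {
  ps <- g2p("διαβάτης")
  expect_identical(
    as_ipa(ps)$phones,
    c("ð", "ʝ", "a", "v", "a", "t", "i", "s")
  )
  expect_identical(as_ipa(c("δ", "γ", "ε", "k")), c("ð", "ɣ", "e", "k"))
})

test_that("transcribe() returns a tidy table", {
  tbl <- transcribe(c("γυάλα", "αντένα"))
  expect_s3_class(tbl, "tbl_df")
  expect_identical(tbl$transcription, c("ʝ'ala", "ad'εna"))
  expect_identical(tbl$stress, c(2L, 3L))
})
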