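test_that("onset inventories are maximal prefixes, prefix-closed", {
  expect_setequal(build_onset_inventory(c("θρόνος", "πατέρας")), c("θρ", "θ", "π"))
  expect_setequal(build_onset_inventory("αέρας"), character(0))
  expect_setequal(build_onset_inventory("στρατός"), c("στρ", "στ", "σ"))
})

test_that("orthographic syllabification follows the school-grammar rule", {
  expect_identical(syllabify_orth("θάλασσα")$units, c("θά", "λασ", "σα"))
  expect_identical(syllabify_orth("πατέρας")$units, c("πα", "τέ", "ρας"))
  expect_identical(syllabify_orth("άνθρωπος")$units, c("άν", "θρω", "πος"))
  expect_identical(syllabify_orth("γυάλα")$units, c("γυά", "λα"))
  expect_identical(syllabify_orth("κυάνιο")$units, c("κυ", "ά", "νι", "ο"))
  expect_identical(syllabify_orth("καμβάς")$units, c("καμ", "βάς"))

  s <- syllabify_orth("θάλασσα")
  expect_identical(s$stressed, 1L)
  expect_error(syllabify_orth("βγρ"), "no vowel nucleus")
})

test_that("cluster legality matches the stated verdicts", {
  expect_false(cluster_is_legal_onset(c("m", "v")))
  expect_false(cluster_is_legal_onset(c("r", "m")))
  expect_false(cluster_is_legal_onset(c("r", "p")))
  expect_true(cluster_is_legal_onset("p"))
  expect_true(cluster_is_legal_onset(c("θ", "r")))
  expect_true(cluster_is_legal_onset(c("p", "s", "ç")))
  expect_true(cluster_is_legal_onset(c("δ", "ʝ")))

  # the permissive preset flips the nasal/liquid verdicts
  expect_true(cluster_is_legal_onset(c("m", "v"), iplr_rules()))
  expect_true(cluster_is_legal_onset(c("r", "m"), iplr_rules()))
  expect_true(cluster_is_legal_onset(c("r", "p"), iplr_rules()))

  # every verdict carries a reason
  for (cl in list("p", c("m", "v"), c("θ", "r"))) {
    expect_match(attr(cluster_is_legal_onset(cl), "reason"), ".+")
  }
  expect_error(cluster_is_legal_onset(c("p", "Q")), "no consonant profile")

  # voicing disagreement between obstruents splits on its own
  expect_false(cluster_is_legal_onset(c("v", "t")))
  expect_true(cluster_is_legal_onset(c("v", "t"), cluster_rules(voicing_split = FALSE)))

  # whitelist overrides the scales
  expect_true(cluster_is_legal_onset(c("s", "t"), cluster_rules(whitelist = "st")))
  expect_false(cluster_is_legal_onset(c("s", "t")))
})

test_that("phonological syllabification maximises legal onsets", {
  s <- syllabify_phon(g2p("καμβάς"))
  expect_identical(s$units, c("kam", "vas"))
  expect_identical(s$stressed, 2L)

  expect_identical(syllabify_phon(g2p("άρμα"))$units, c("ar", "ma"))
  expect_identical(syllabify_phon(g2p("άρπα"))$units, c("ar", "pa"))
  expect_identical(syllabify_phon(g2p("γυάλα"))$units, c("ʝa", "la"))
  expect_identical(syllabify_phon(g2p("κυάνιο"))$units, c("ci", "a", "ni", "o"))
  expect_identical(syllabify_phon(g2p("κλεψιά"))$units, c("klε", "psça"))
  expect_identical(syllabify_phon(g2p("διαβάτης"))$units, c("δʝa", "va", "tis"))
  expect_identical(syllabify_phon(g2p("άνθρωπος"))$units, c("an", "θro", "pos"))

  # IPLR-style rules keep [mv] and [rm] whole
  expect_identical(
    syllabify_phon(g2p("καμβάς"), iplr_rules())$units,
    c("ka", "mvas")
  )
  expect_identical(
    syllabify_phon(g2p("άρμα"), iplr_rules())$units,
    c("a", "rma")
  )
})

test_that("syllabification invariants hold on generated words", {
  lex <- simulate_lexicon(300, theta = 0.9, seed = 42)
  rules <- cluster_rules()
  for (i in seq_len(nrow(lex))) {
    w <- lex$word[i]
    orth <- syllabify_orth(w)
    expect_identical(paste(orth$units, collapse = ""), w)
    # exactly one vowel-grapheme group per orthographic unit
    n_groups <- vapply(orth$units, function(u) {
      t <- hellex:::gk_tokenize(u)
      sum(t$type == "vowel")
    }, integer(1))
    expect_true(all(n_groups == 1L), label = paste("one nucleus:", w))

    ps <- g2p(w)
    phon <- syllabify_phon(ps, rules)
    expect_identical(paste(phon$units, collapse = ""), paste(ps$phones, collapse = ""))
    up <- attr(phon, "unit_phones")
    # onset legality and maximality
    for (u in seq_along(up)[-1]) {
      unit <- up[[u]]
      v_at <- which(unit %in% c("a", "ε", "i", "o", "u"))[1]
      onset <- unit[seq_len(v_at - 1L)]
      if (length(onset) > 1) {
        expect_true(cluster_is_legal_onset(onset, rules), label = paste("onset", w))
      }
      prev <- up[[u - 1]]
      v_prev <- max(which(prev %in% c("a", "ε", "i", "o", "u")))
      coda <- prev[seq_along(prev) > v_prev]
      if (length(coda) > 0) {
        expect_false(
          isTRUE(cluster_is_legal_onset(c(coda[length(coda)], onset), rules)),
          label = paste("maximality", w)
        )
      }
    }
  }
})

test_that("orthographic and phonological unit counts agree on CiV-free words", {
  lex <- simulate_lexicon(200, theta = 0.9, seed = 7)
  expect_identical(
    vapply(lex$word, function(w) n_syllables(syllabify_orth(w)), integer(1), USE.NAMES = FALSE),
    vapply(lex$word, function(w) n_syllables(syllabify_phon(g2p(w))), integer(1), USE.NAMES = FALSE)
  )
})

test_that("CiV majorities count parses and break ties towards two", {
  lex <- tibble::tibble(
    word = c(rep("κυάνιο", 1), "γυάλα", "νιώθω", "ποτήρια", "βιολί"),
    orth_syll = c("κυ-ά-νι-ο", "γυά-λα", "νιώ-θω", "πο-τή-ρια", "βι-ο-λί")
  )
  tab <- civ_majority(lex)
  # ιο: split in κυάνιο and βιολί, not counted elsewhere
  expect_identical(tab$majority[tab$cluster == "ιο"], "two")
  expect_identical(tab$n_two[tab$cluster == "ιο"], 2L)
  # υα: one in γυάλα, two in κυάνιο -> tie resolves to two
  expect_identical(tab$n_one[tab$cluster == "υα"], 1L)
  expect_identical(tab$n_two[tab$cluster == "υα"], 1L)
  expect_identical(tab$majority[tab$cluster == "υα"], "two")
  # ια: merged in ποτήρια
  expect_identical(tab$majority[tab$cluster == "ια"], "one")
  # absent cluster -> no row
  expect_false("ιε" %in% tab$cluster)
})

test_that("CiV resolution precedence: exception > majority > fallback", {
  pol <- civ_policy(
    stats = tibble::tibble(cluster = "υα", majority = "two"),
    exceptions = tibble::tibble(word = "γυαλα", parse = "one"),
    fallback = "error"
  )
  r <- resolve_civ("γυάλα", pol)
  expect_identical(r$parse, "one")
  expect_identical(r$source, "exception")

  r2 <- resolve_civ("κυάλα", pol) # not in exceptions; υα majority applies
  expect_identical(r2$parse, "two")
  expect_identical(r2$source, "majority")

  expect_error(resolve_civ("νιώθω", pol), "unresolved CiV")
  r3 <- resolve_civ("νιώθω", civ_policy(stats = NULL, exceptions = NULL, fallback = "two"))
  expect_identical(r3$source, "fallback")
})

test_that("the default policy parses the curated synizesis words as one syllable", {
  expect_identical(resolve_civ("νιώθω")$parse, "one")
  expect_identical(resolve_civ("κυάνιο")$parse, c("two", "two"))
  expect_identical(n_syllables(syllabify_orth("διαβάτης")), 3L)
})
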