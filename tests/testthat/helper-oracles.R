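# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca)
  nb <- length(cb)
  d <- matrix(0L, na + 1, nb + 1)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1L,
        d[i + 1, j] + 1L,
        d[i, j] + (ca[i] != cb[j])
      )
    }
  }
  d[na + 1, nb + 1]
}

oracle_coltheart <- function(word, lexicon) {
  w <- gsub("ς", "σ", word)
  lex <- unique(gsub("ς", "σ", lexicon))
  n <- 0L
  cw <- strsplit(w, "")[[1]]
  for (e in lex) {
    if (nchar(e) != nchar(w) || e == w) next
    if (sum(strsplit(e, "")[[1]] != cw) == 1L) n <- n + 1L
  }
  n
}

oracle_old20 <- function(word, lexicon, k = 20) {
  w <- gsub("ς", "σ", word)
  lex <- setdiff(unique(gsub("ς", "σ", lexicon)), w)
  d <- sort(vapply(lex, oracle_levenshtein, numeric(1), a = w))
  mean(d[seq_len(k)])
}

# pairwise-agreement derivation of Fleiss' kappa (a different route to the
# same statistic: per-item agreement as agreeing rater pairs / all pairs)
oracle_fleiss <- function(m) {
  n <- sum(m[1, ])
  N <- nrow(m)
  p_i <- apply(m, 1, function(r) sum(choose(r, 2)) / choose(n, 2))
  p_bar <- mean(p_i)
  p_j <- colSums(m) / sum(m)
  p_e <- sum(p_j^2)
  (p_bar - p_e) / (1 - p_e)
}

oracle_rime_neighbourhood <- function(lexicon) {
  vapply(seq_len(nrow(lexicon)), function(i) {
    sum(
      lexicon$rime[-i] == lexicon$rime[i] &
        lexicon$stress_position[-i] == lexicon$stress_position[i],
      na.rm = TRUE
    )
  }, integer(1))
}

oracle_stress_props <- function(lexicon) {
  out <- list()
  for (e in unique(lexicon$ending)) {
    g <- lexicon[lexicon$ending == e, ]
    for (p in unique(g$stress_position)) {
      out[[paste(e, p)]] <- tibble::tibble(
        ending = e, stress_position = p,
        prop_type = sum(g$stress_position == p) / nrow(g),
        prop_token = sum(g$freq_count[g$stress_position == p]) / sum(g$freq_count)
      )
    }
  }
  dplyr::bind_rows(out)
}

# small random Greek-like letter strings for metric oracles (not necessarily
# phonotactically well-formed; the metrics are defined on plain strings)
random_greek_strings <- function(n, min_len = 3, max_len = 8) {
  letters_pool <- strsplit("αβγδεζηθικλμνξοπρστυφχψω", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(letters_pool, sample(min_len:max_len, 1), replace = TRUE),
      collapse = ""
    )
  }, character(1))
}
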