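test_that("multi-word dictionary terms are joined with underscores", {
  d <- term_dictionary("chipping sparrows")
  expect_equal(tag_terms(c("chipping", "sparrows"), d), "chipping_sparrows")
  expect_equal(tag_terms(c("saw", "chipping", "sparrows", "today"), d),
               c("saw", "chipping_sparrows", "today"))
})

test_that("longest match wins and empty dictionaries are the identity", {
  d <- term_dictionary(c("Panthera", "Panthera leo"), "scientific")
  expect_equal(tag_terms(c("Panthera", "leo"), d), "Panthera_leo")
  expect_equal(tag_terms(c("Panthera", "tigris"), d),
               c("Panthera", "tigris"))
  d0 <- term_dictionary(character())
  toks <- c("no", "names", "here")
  expect_equal(tag_terms(toks, d0), toks)
})

test_that("case policy: genus initial is case-sensitive, vernaculars are not", {
  d <- term_dictionary(c("Panthera leo", "tree swallow"),
                       c("scientific", "vernacular"))
  idx <- build_dict_index(d)
  expect_equal(tag_terms(c("Panthera", "LEO"), idx), "Panthera_leo")
  expect_equal(tag_terms(c("panthera", "leo"), idx), c("panthera", "leo"))
  expect_equal(tag_terms(c("Tree", "Swallow"), idx), "tree_swallow")
})

test_that("re-tagging a tagged document is idempotent", {
  d <- term_dictionary(c("chipping sparrows", "Panthera leo"),
                       c("vernacular", "scientific"))
  idx <- build_dict_index(d)
  toks <- c("a", "chipping", "sparrows", "met", "Panthera", "leo")
  once <- tag_terms(toks, idx)
  expect_equal(tag_terms(once, idx), once)
})

test_that("token-count conservation holds under tagging", {
  b <- fixture_synth()
  tagged <- tag_corpus(b$corpus, b$dictionary)
  idx_lens <- vapply(b$dictionary$name, function(nm)
    length(tokenize_text(nm)), integer(1))
  for (i in seq_along(b$corpus)) {
    orig <- b$corpus[[i]]
    out <- tagged$documents[[i]]
    joined <- out[grepl("_", out, fixed = TRUE)]
    shrink <- sum(vapply(joined, function(t) length(split_term(t)) - 1L,
                         integer(1)))
    expect_equal(length(out), length(orig) - shrink)
  }
})

test_that("term frequencies equal a brute-force sliding-window count", {
  b <- fixture_synth()
  tagged <- tag_corpus(b$corpus, b$dictionary)
  freqs <- term_frequencies(tagged)
  # brute force: count occurrences of each name's token sequence in raw text
  for (nm in b$dictionary$name) {
    comps <- tokenize_text(nm)
    k <- length(comps)
    n_brute <- 0L
    for (d in b$corpus) {
      if (length(d) < k) next
      for (i in seq_len(length(d) - k + 1L)) {
        if (all(d[i:(i + k - 1L)] == comps)) n_brute <- n_brute + 1L
      }
    }
    surf <- term_surface(nm)
    got <- if (surf %in% names(freqs)) unname(freqs[[surf]]) else 0L
    expect_equal(got, n_brute, info = nm)
  }
})

test_that("select_terms applies an inclusive threshold", {
  freqs <- c(a = 5L, b = 4L, c = 50L)
  expect_equal(select_terms(freqs, 5), c("a", "c"))
  expect_setequal(select_terms(freqs, 1), c("a", "b", "c"))
  expect_equal(select_terms(freqs, 50), "c")
  expect_error(select_terms(freqs, 0), "min_freq")
})

test_that("underscores in source text are escaped before joining", {
  d <- term_dictionary("odd_name species")
  out <- tag_terms(c("odd_name", "species"), d)
  expect_length(out, 1L)
  expect_equal(split_term(out), c("odd_name", "species"))
})
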