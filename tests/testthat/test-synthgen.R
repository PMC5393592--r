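test_that("generation is deterministic and bookkeeping matches the config", {
  cfg <- synth_config(vocab_size = 500, n_docs = 30, doc_length = 100,
                      n_groups = 5, group_size = 2, seed = 77)
  a <- synth_generate(cfg)
  b <- synth_generate(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synth(a, d1); write_synth(b, d2)
  for (f in c("corpus.txt", "dictionary.tsv", "gold.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_equal(a$manifest$n_groups, 5L)
  expect_equal(a$manifest$n_members, 10L)
  expect_equal(length(a$gold), 5L)
  expect_equal(nrow(a$dictionary), 10L)
  expect_length(a$corpus, 30L)
  # generator does not disturb the session RNG
  set.seed(1); x <- runif(1)
  set.seed(1); synth_generate(cfg); y <- runif(1)
  expect_identical(x, y)
})

test_that("shared-component benchmark controls component sharing exactly", {
  cfg <- synth_config(vocab_size = 500, n_docs = 10, doc_length = 100,
                      n_groups = 8, seed = 3)
  all_shared <- make_shared_component_benchmark(cfg, shared_component_prob = 1)
  frac <- function(x) mean(vapply(x$manifest$groups, function(g) {
    comps <- strsplit(g$members, " ", fixed = TRUE)
    length(intersect(comps[[1]], comps[[2]])) > 0
  }, logical(1)))
  expect_equal(frac(all_shared), 1)
  # every member is a two-word name sharing exactly one component
  for (g in all_shared$manifest$groups) {
    comps <- strsplit(g$members, " ", fixed = TRUE)
    expect_true(all(lengths(comps) == 2))
    expect_length(intersect(comps[[1]], comps[[2]]), 1L)
  }
  none_shared <- make_shared_component_benchmark(cfg, shared_component_prob = 0)
  expect_equal(frac(none_shared), 0)
})

test_that("background unigram distribution is Zipfian with the configured exponent", {
  cfg <- synth_config(vocab_size = 1000, n_docs = 600, doc_length = 200,
                      n_groups = 2, signature_size = 5, plants_per_doc = 1,
                      component_background_rate = 0, zipf_exponent = 1.1,
                      seed = 13)
  x <- synth_generate(cfg)
  toks <- unlist(x$corpus, use.names = FALSE)
  toks <- toks[startsWith(toks, "w")] # background words only
  tab <- sort(table(toks), decreasing = TRUE)
  r <- seq_along(tab)
  keep <- r <= 200 # head of the distribution, where counts are stable
  fit <- stats::lm(log(as.numeric(tab[keep])) ~ log(r[keep]))
  expect_equal(unname(coef(fit)[2]), -1.1, tolerance = 0.15)
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(vocab_size = 100, n_groups = 20,
                            signature_size = 10), "infeasible")
  expect_error(synth_config(signature_rate = 1.5), "probabilities")
  expect_error(synth_config(group_size = 1), "group_size")
  expect_error(synth_config(signature_pool_size = 5, signature_size = 10),
               "pool_size")
})

test_that("planted gold maps every member to its partners", {
  x <- fixture_synth()
  gold <- planted_gold(x)
  expect_length(gold, x$manifest$n_members)
  for (g in x$manifest$groups) {
    for (m in g$members) expect_setequal(gold[[m]], setdiff(g$members, m))
  }
})
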