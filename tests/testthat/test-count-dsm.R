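test_that("window counts match exhaustive enumeration on small documents", {
  doc <- list(d1 = c("a", "b", "c"))
  m1 <- cooccurrence_counts(doc, window = 1L)
  expect_equal(m1$grand_total, 4L)
  expect_equal(m1$pairs$n[m1$pairs$term == "a" & m1$pairs$context == "b"], 1L)
  expect_equal(m1$pairs$n[m1$pairs$term == "b" & m1$pairs$context == "c"], 1L)
  expect_equal(nrow(m1$pairs), 4L)

  # single-token documents have no neighbours
  m0 <- cooccurrence_counts(list(d = "a"), window = 5L)
  expect_equal(m0$grand_total, 0L)

  m2 <- cooccurrence_counts(doc, window = 2L)
  oracle <- oracle_cooccurrence(doc, 2L)
  expect_equal(m2$grand_total, sum(unlist(oracle)))
  for (key in names(oracle)) {
    tc <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    expect_equal(m2$pairs$n[m2$pairs$term == tc[1] & m2$pairs$context == tc[2]],
                 oracle[[key]])
  }
})

test_that("count conservation and window enumeration hold on a generated corpus", {
  b <- fixture_synth()
  tagged <- tag_corpus(b$corpus, b$dictionary)
  docs <- tagged$documents[1:8] # <= 10^4 tokens
  for (w in c(1L, 3L)) {
    m <- cooccurrence_counts(docs, window = w)
    expect_equal(m$grand_total, sum(m$pairs$n))
    expect_equal(m$grand_total, sum(m$term_totals))
    expect_equal(m$grand_total, sum(m$context_totals))
    oracle <- oracle_cooccurrence(docs, w)
    expect_equal(m$grand_total, sum(unlist(oracle)))
    # spot-check every pair of one term plus total pair count
    expect_equal(nrow(m$pairs), length(oracle))
  }
})

test_that("llr matches the literal G2 formula and clips negative association", {
  # observed equals expected under independence -> 0
  expect_equal(llr(10, 90, 90, 810), 0)
  # high-precision direct evaluation
  expect_equal(llr(10, 20, 30, 940), oracle_g2(10, 20, 30, 940),
               tolerance = 1e-12)
  # negative association clipped (k11 below expectation)
  expect_equal(llr(0, 5, 5, 90), 0)
  expect_gt(llr(0, 5, 5, 90, clip = FALSE), 0)
  expect_error(llr(0, 0, 0, 0), "all-zero")
  expect_error(llr(-1, 2, 3, 4), "non-negative")
})

test_that("llr is symmetric under table transposition and non-negative (random tables)", {
  set.seed(101)
  for (i in 1:200) {
    k <- as.numeric(rpois(4, lambda = c(5, 40, 40, 400)))
    if (sum(k) == 0) next
    v <- llr(k[1], k[2], k[3], k[4], clip = FALSE)
    vt <- llr(k[1], k[3], k[2], k[4], clip = FALSE)
    expect_gte(v, 0)
    expect_equal(v, vt, tolerance = 1e-9)
    expect_equal(v, oracle_g2(k[1], k[2], k[3], k[4]), tolerance = 1e-9)
  }
})

test_that("count vectors select top-d contexts and reproduce brute-force llr entries", {
  docs <- list(d1 = c("x", "a", "b", "x", "a", "c"),
               d2 = c("b", "x", "a", "a", "b", "y"))
  model <- cooccurrence_counts(docs, window = 2L)
  sp <- build_count_vectors(model, dsm_config(window = 2L, dim = 3L))
  expect_equal(ncol(sp$vectors), 3L)
  # retained units are the 3 with largest context totals (ties lexicographic)
  ct <- sort(model$context_totals, decreasing = TRUE)
  expect_setequal(colnames(sp$vectors),
                  names(ct)[order(-ct, names(ct))][1:3])
  # every entry equals llr of the brute-force table
  N <- model$grand_total
  for (tm in rownames(sp$vectors)) {
    for (u in colnames(sp$vectors)) {
      k11 <- model$pairs$n[model$pairs$term == tm & model$pairs$context == u]
      if (length(k11) == 0L) k11 <- 0L
      tt <- model$term_totals[[tm]]
      cc <- model$context_totals[[u]]
      exp_val <- if (k11 == 0L) 0 else llr(k11, tt - k11, cc - k11, N - tt - cc + k11)
      expect_equal(sp$vectors[tm, u], exp_val, tolerance = 1e-9,
                   info = paste(tm, u))
    }
  }
  # dim larger than distinct units degrades gracefully
  sp_all <- build_count_vectors(model, dsm_config(dim = 10000L))
  expect_equal(ncol(sp_all$vectors), length(model$context_totals))
  # a term restricted out of the space is absent
  sp_sub <- build_count_vectors(model, dsm_config(dim = 5L), terms = "a")
  expect_equal(rownames(sp_sub$vectors), "a")
})

test_that("end-to-end count vectors on a fixture equal an independent reimplementation", {
  b <- fixture_synth()
  tagged <- tag_corpus(b$corpus, b$dictionary)
  docs <- tagged$documents[1:6]
  model <- cooccurrence_counts(docs, window = 3L)
  sp <- build_count_vectors(model, dsm_config(window = 3L, dim = 50L))
  oracle <- oracle_cooccurrence(docs, 3L)
  N <- sum(unlist(oracle))
  terms <- sample(rownames(sp$vectors), 5L)
  for (tm in terms) {
    for (u in colnames(sp$vectors)[1:10]) {
      k11 <- oracle[[paste0(tm, "\r", u)]] %||% 0L
      tt <- sum(unlist(oracle[startsWith(names(oracle), paste0(tm, "\r"))]))
      cc <- sum(unlist(oracle[endsWith(names(oracle), paste0("\r", u))]))
      exp_val <- if (k11 == 0) 0 else {
        g <- oracle_g2(k11, tt - k11, cc - k11, N - tt - cc + k11)
        if (k11 < tt * cc / N) 0 else g
      }
      expect_equal(sp$vectors[tm, u], exp_val, tolerance = 1e-9)
    }
  }
})
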