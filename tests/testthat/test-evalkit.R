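rc <- function(query, terms) {
  ranked_candidates(query, terms, seq(1, 0.5, length.out = length(terms)))
}

test_that("top-N accuracy counts queries with at least one gold hit in the top N", {
  gold <- structure(list(q1 = "x", q2 = "p"), class = "reference_standard")
  rankings <- list(rc("q1", c("y", "x", "z")), rc("q2", c("q", "r", "s")))
  expect_equal(top_n_accuracy(rankings, gold, 3), 0.5)
  expect_equal(top_n_accuracy(rankings, gold, 1), 0)
  all_hit <- list(rc("q1", c("x", "y")), rc("q2", c("p", "q")))
  expect_equal(top_n_accuracy(all_hit, gold, 1), 1)
  expect_error(top_n_accuracy(list(rc("zz", "a")), gold, 1), "missing")
})

test_that("precision and recall at N follow the standard definitions", {
  r <- rc("q", c("a", "x", "y", "z", "w"))
  pr <- precision_recall_at_n(r, c("a", "b"), 5)
  expect_equal(unname(pr["precision"]), 0.2)
  expect_equal(unname(pr["recall"]), 0.5)
  none <- precision_recall_at_n(rc("q", c("u", "v")), c("a", "b"), 2)
  expect_equal(unname(none), c(0, 0))
  perfect <- precision_recall_at_n(rc("q", c("a", "b")), c("a", "b"), 2)
  expect_equal(unname(perfect), c(1, 1))
  expect_error(precision_recall_at_n(r, character(), 3), "empty gold")
})

test_that("average precision enumerates precision at hit ranks", {
  expect_equal(average_precision(rc("q", c("a", "x", "b", "y")), c("a", "b")),
               (1 / 1 + 2 / 3) / 2)
  expect_equal(average_precision(rc("q", c("a", "b", "x")), c("a", "b")), 1)
  expect_equal(average_precision(rc("q", c("x", "y")), c("a", "b")), 0)
})

test_that("gold comparison is case- and underscore-insensitive", {
  gold <- structure(list("Actitis macularius" = c("Tringa macularia",
                                                  "spotted sandpiper")),
                    class = "reference_standard")
  r <- rc("Actitis_macularius", c("spotted_sandpiper", "other_bird"))
  expect_equal(top_n_accuracy(list(r), gold, 1), 1)
  rep <- evaluate_model(list(r), gold)
  expect_equal(rep$per_n$accuracy[rep$per_n$n == 1], 1)
})

test_that("all metrics equal the brute-force oracle on seeded random fixtures", {
  set.seed(59)
  for (trial in 1:100) {
    pool <- sprintf("c%02d", 1:20)
    n_gold <- sample(1:4, 1)
    gold_set <- sample(pool, n_gold)
    ranked <- sample(pool, sample(5:20, 1))
    r <- rc("q", ranked)
    gold <- structure(list(q = gold_set), class = "reference_standard")
    for (n in c(1, 3, 5, 10)) {
      o <- oracle_metrics(ranked, gold_set, n)
      pr <- precision_recall_at_n(r, gold_set, n)
      expect_equal(unname(pr["precision"]), o$precision)
      expect_equal(unname(pr["recall"]), o$recall)
      expect_equal(top_n_accuracy(list(r), gold, n), as.numeric(o$hit))
      # precision * N and recall * |gold| are integer counts
      expect_equal(pr[["precision"]] * n, round(pr[["precision"]] * n))
      expect_equal(pr[["recall"]] * n_gold, round(pr[["recall"]] * n_gold))
    }
    expect_equal(average_precision(r, gold_set),
                 oracle_metrics(ranked, gold_set, 1)$ap, tolerance = 1e-12)
  }
})

test_that("evaluate_model aggregates per-N metrics, MAP and vocabulary restriction", {
  gold <- structure(list(q1 = c("a", "zz_not_in_vocab"), q2 = "b",
                         q3 = "only_oov"),
                    class = "reference_standard")
  rankings <- list(rc("q1", c("a", "x")), rc("q2", c("y", "b")),
                   rc("q3", c("x", "y")))
  vocab <- c("a", "b", "x", "y", "q1", "q2", "q3")
  rep <- evaluate_model(rankings, gold, n_range = 1:5, vocab = vocab)
  # q3 has no in-vocabulary gold: excluded but counted
  expect_equal(rep$n_queries, 2L)
  expect_equal(rep$n_excluded, 1L)
  expect_equal(rep$n_gold_total, 4L)
  expect_equal(rep$n_gold_in_vocab, 2L)
  # MAP is the mean of per-query AP (restricted gold)
  expect_equal(rep$map, mean(c(1, 1 / 2)))
  # monotonicity in N
  expect_true(all(diff(rep$per_n$recall) >= 0))
  expect_true(all(diff(rep$per_n$accuracy) >= 0))
  # single-query MAP equals that query's AP
  one <- evaluate_model(rankings[1], gold, vocab = vocab)
  expect_equal(one$map, unname(one$ap[1]))
})
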