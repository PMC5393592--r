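# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# exhaustive window enumeration: for every ordered position pair within
# distance w in the same document, count (token_i, token_j)
oracle_cooccurrence <- function(docs, w) {
  pairs <- list()
  for (d in docs) {
    n <- length(d)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (abs(i - j) <= w) {
          key <- paste0(d[[i]], "\r", d[[j]])
          pairs[[key]] <- (pairs[[key]] %||% 0L) + 1L
        }
      }
    }
  }
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# literal four-term G^2 sum
oracle_g2 <- function(k11, k12, k21, k22) {
  k <- c(k11, k12, k21, k22)
  n <- sum(k)
  rows <- c(k11 + k12, k11 + k12, k21 + k22, k21 + k22)
  cols <- c(k11 + k21, k12 + k22, k11 + k21, k12 + k22)
  e <- rows * cols / n
  terms <- ifelse(k > 0, k * log(k / e), 0)
  2 * sum(terms)
}

# literal additive composition: sum of L2-normalized rows
oracle_bam <- function(mat) {
  out <- rep(0, ncol(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    out <- out + v / sqrt(sum(v^2))
  }
  out
}

# full-sort cosine ranking
oracle_top_n <- function(query, mat, pool, n) {
  q <- mat[query, ]
  pool <- setdiff(pool, query)
  scores <- vapply(pool, function(p) {
    v <- mat[p, ]
    sum(q * v) / sqrt(sum(q^2) * sum(v^2))
  }, numeric(1))
  ord <- order(-scores, pool, method = "radix")
  data.frame(term = pool[ord][seq_len(min(n, length(pool)))],
             score = scores[ord][seq_len(min(n, length(pool)))],
             stringsAsFactors = FALSE)
}

# naive retrieval metrics over one ranking (character vectors, exact match)
oracle_metrics <- function(ranked, gold, n) {
  top <- head(ranked, n)
  tp <- length(intersect(top, gold))
  hits <- which(ranked %in% gold)
  ap <- if (length(hits) == 0) 0 else {
    sum(vapply(seq_along(hits), function(i) i / hits[[i]], numeric(1))) / length(gold)
  }
  list(precision = tp / n, recall = tp / length(gold),
       hit = tp > 0, ap = ap)
}

# small deterministic fixture corpus with two planted name pairs
fixture_synth <- function(seed = 42) {
  synth_generate(synth_config(vocab_size = 300, n_docs = 40, doc_length = 120,
                              n_groups = 4, signature_size = 8,
                              plants_per_doc = 4, seed = seed))
}
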