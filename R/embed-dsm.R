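# Prediction-based distributional models (CBOW and GloVe-style), trained by
# seeded single-threaded compiled routines. Identical seed and configuration
# give bitwise-identical vectors.

#' Token frequencies over a corpus
#'
#' Counts every token (context words and tagged terms alike); this defines
#' the training vocabulary of the prediction-based models.
#'
#' @param docs a `tagged_corpus` or list of token vectors.
#' @return named integer vector.
#' @export
token_frequencies <- function(docs) {
  if (inherits(docs, "tagged_corpus")) docs <- docs$documents
  tab <- table(unlist(docs, use.names = FALSE))
  stats::setNames(as.integer(tab), names(tab))
}

embed_vocab <- function(docs, min_count) {
  freqs <- token_frequencies(docs)
  vocab <- select_terms(freqs, max(1L, min_count))
  if (length(vocab) == 0L) {
    stop("empty vocabulary after min_count filtering", call. = FALSE)
  }
  f <- freqs[vocab]
  vocab <- vocab[order(-f, vocab, method = "radix")]
  list(vocab = vocab, counts = as.numeric(freqs[vocab]))
}

#' Train continuous bag-of-words embeddings
#'
#' CBOW with negative sampling: the model predicts a token from the average
#' of the embedding vectors of its context window. Training is
#' single-threaded with an internal seeded RNG, so runs with the same seed
#' and configuration are bitwise reproducible.
#'
#' @param docs a `tagged_corpus` or list of token vectors (already tagged and
#'   normalized).
#' @param cfg a `dsm_config`; `dim` is the embedding size (300 at full
#'   corpus scale), `window` the context size, `min_count` the vocabulary
#'   threshold, `seed` the RNG seed.
#' @param epochs training passes over the corpus.
#' @param negative negative samples per positive example.
#' @param alpha initial learning rate (linear decay).
#' @return a `vector_space` over the vocabulary.
#' @export
train_cbow <- function(docs, cfg = dsm_config(), epochs = 10L, negative = 5L,
                       alpha = 0.05) {
  if (inherits(docs, "tagged_corpus")) docs <- docs$documents
  vb <- embed_vocab(docs, cfg$min_count)
  idx <- stats::setNames(seq_along(vb$vocab), vb$vocab)
  iddocs <- lapply(docs, function(d) {
    ids <- unname(idx[d])
    ids <- ids[!is.na(ids)]
    as.integer(ids)
  })
  iddocs <- iddocs[lengths(iddocs) > 0L]
  m <- cpp_train_cbow(iddocs, length(vb$vocab), vb$counts, cfg$dim,
                      cfg$window, as.integer(epochs), as.integer(negative),
                      alpha, cfg$seed)
  rownames(m) <- vb$vocab
  vector_space(m, provenance = list(model = "cbow", window = cfg$window,
                                    dim = cfg$dim, min_count = cfg$min_count,
                                    epochs = epochs, negative = negative,
                                    alpha = alpha, seed = cfg$seed))
}

#' Train GloVe-style global vectors
#'
#' Weighted least-squares factorization of log co-occurrence counts (built
#' with [cooccurrence_counts()] at the configured window), optimized by
#' AdaGrad over shuffled nonzero pairs. Word and context vectors are summed
#' for the final representation. Same-seed runs are bitwise reproducible.
#'
#' @inheritParams train_cbow
#' @param x_max weighting cutoff of the loss (co-occurrence counts above
#'   `x_max` get full weight).
#' @param weight_alpha exponent of the weighting function.
#' @param eta AdaGrad learning rate.
#' @return a `vector_space` over the vocabulary.
#' @export
train_glove <- function(docs, cfg = dsm_config(), epochs = 15L, x_max = 100,
                        weight_alpha = 0.75, eta = 0.05) {
  if (inherits(docs, "tagged_corpus")) docs <- docs$documents
  vb <- embed_vocab(docs, cfg$min_count)
  model <- cooccurrence_counts(docs, window = cfg$window)
  pairs <- model$pairs[model$pairs$term %in% vb$vocab &
                         model$pairs$context %in% vb$vocab, ]
  if (nrow(pairs) == 0L) stop("no co-occurrence pairs within vocabulary",
                              call. = FALSE)
  ia <- match(pairs$term, vb$vocab)
  ja <- match(pairs$context, vb$vocab)
  m <- cpp_train_glove(as.integer(ia), as.integer(ja), as.numeric(pairs$n),
                       length(vb$vocab), cfg$dim, as.integer(epochs),
                       x_max, weight_alpha, eta, cfg$seed)
  rownames(m) <- vb$vocab
  vector_space(m, provenance = list(model = "glove", window = cfg$window,
                                    dim = cfg$dim, min_count = cfg$min_count,
                                    epochs = epochs, x_max = x_max,
                                    weight_alpha = weight_alpha, eta = eta,
                                    seed = cfg$seed))
}
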