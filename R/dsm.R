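#' Fit a distributional semantic model over a corpus
#'
#' The single front-end to the six model variants: count-based association
#' vectors, CBOW and GloVe-style embeddings, each either directly over
#' underscore-joined multi-word terms (`compose = FALSE`) or over
#' single-word vectors combined by the basic additive model
#' (`compose = TRUE`). The corpus is tagged against the dictionary, context
#' tokens are normalized, the chosen model is trained and (optionally)
#' composed.
#'
#' @param corpus named list of token vectors (see [read_corpus()]).
#' @param dictionary a `term_dictionary` of species names.
#' @param method `"count"`, `"cbow"` or `"glove"`.
#' @param compose use the basic additive model: train single-word vectors on
#'   the untagged corpus and compose multi-word term vectors from their
#'   components.
#' @param config a `dsm_config` (window, dimension, min_count, seed).
#' @param normalize a `norm_config`, or `NULL` to skip normalization.
#' @param ... passed to the trainer ([build_count_vectors()],
#'   [train_cbow()] or [train_glove()]): e.g. `epochs`, `negative`,
#'   `x_max`.
#' @return object of class `dsm`: list with `space` (a `vector_space`
#'   restricted to dictionary terms plus, for reference, the full trained
#'   space in `full_space`), `freqs` (term corpus frequencies),
#'   `dictionary`, `method`, `compose`, `config`.
#' @examples
#' bench <- synth_generate(synth_config(n_docs = 50, n_groups = 5))
#' fit <- dsm(bench$corpus, bench$dictionary, method = "count",
#'            config = dsm_config(dim = 500, min_count = 2))
#' print(fit)
#' predict(fit, newdata = names(bench$gold)[1], n = 3)
#' @export
dsm <- function(corpus, dictionary, method = c("count", "cbow", "glove"),
                compose = FALSE, config = dsm_config(),
                normalize = norm_config(), ...) {
  method <- match.arg(method)
  tagged <- tag_corpus(corpus, dictionary)
  freqs <- term_frequencies(tagged)
  surfaces <- tagged$terms

  if (compose) {
    comp_words <- unique(unlist(lapply(surfaces, split_term)))
    train_docs <- corpus
    protect <- comp_words
  } else {
    train_docs <- tagged$documents
    protect <- surfaces
  }
  if (!is.null(normalize)) {
    train_docs <- normalize_corpus(train_docs, cfg = normalize,
                                   protect = protect)
  }

  dots <- list(...)
  keep_args <- function(fn) dots[intersect(names(dots), names(formals(fn)))]
  full <- switch(method,
    count = {
      model <- cooccurrence_counts(train_docs, window = config$window)
      do.call(build_count_vectors,
              c(list(model, cfg = config), keep_args(build_count_vectors)))
    },
    cbow = do.call(train_cbow,
                   c(list(train_docs, cfg = config), keep_args(train_cbow))),
    glove = do.call(train_glove,
                    c(list(train_docs, cfg = config), keep_args(train_glove))))

  space <- if (compose) compose_space(full, surfaces)
           else space_subset(full, surfaces)
  space$provenance$compose <- compose
  structure(list(space = space, full_space = full, freqs = freqs,
                 dictionary = dictionary, method = method, compose = compose,
                 config = config, call = match.call()),
            class = "dsm")
}

#' @export
print.dsm <- function(x, ...) {
  cat("Distributional semantic model (", x$method,
      if (x$compose) "-BAM", ")\n", sep = "")
  cat("  window ", x$config$window, ", dim ", ncol(x$space$vectors),
      ", seed ", x$config$seed, "\n", sep = "")
  cat("  ", nrow(x$space$vectors), " dictionary terms vectorized (of ",
      nrow(x$dictionary), " dictionary entries); vocabulary ",
      nrow(x$full_space$vectors), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dsm <- function(object, ...) {
  f <- object$freqs
  cat("Model: ", object$method, if (object$compose) "-BAM", "\n", sep = "")
  cat("Dictionary terms observed in corpus: ", length(f),
      " (total occurrences ", sum(f), ")\n", sep = "")
  if (length(f) > 0L) {
    cat("Term frequency quartiles:\n")
    print(stats::quantile(f))
  }
  print(object$space)
  invisible(object)
}

#' @export
coef.dsm <- function(object, ...) object$space$vectors

#' Rank related names with a fitted model
#'
#' @param object a fitted `dsm`.
#' @param newdata query term(s); default: every dictionary term in the
#'   space. Plain names with spaces are accepted and converted to their
#'   joined surface.
#' @param n candidates per query.
#' @param pool candidate pool (default: dictionary terms in the space).
#' @param ... unused.
#' @return a single `ranked_candidates` (one query) or a named list of them.
#' @export
predict.dsm <- function(object, newdata = NULL, n = 20L, pool = NULL, ...) {
  vocab <- rownames(object$space$vectors)
  if (is.null(newdata)) newdata <- vocab
  queries <- vapply(newdata, term_surface, "", USE.NAMES = FALSE)
  out <- lapply(queries, top_n, space = object$space, pool = pool, n = n)
  names(out) <- queries
  if (length(out) == 1L) out[[1L]] else out
}
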