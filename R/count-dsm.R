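# Count-based distributional model: windowed co-occurrence counts, Dunning
# G^2 (log-likelihood ratio) association weighting, and pruning of the
# context space to the d most frequent lexical units.

#' Distributional model configuration
#'
#' @param window symmetrical context window in tokens on either side
#'   (default 3, the value used for inventory construction).
#' @param dim number of dimensions: retained context units for the
#'   count-based model (150000 at full corpus scale) or embedding size for
#'   prediction-based models (300).
#' @param min_count minimum corpus frequency for a term to be vectorized.
#' @param seed integer seed controlling all randomness of a training run.
#' @return list of class `dsm_config`.
#' @export
dsm_config <- function(window = 3L, dim = 300L, min_count = 5L, seed = 1L) {
  stopifnot(window >= 1L, dim >= 1L, min_count >= 0L)
  structure(list(window = as.integer(window), dim = as.integer(dim),
                 min_count = as.integer(min_count), seed = as.integer(seed)),
            class = "dsm_config")
}

#' Windowed co-occurrence counts
#'
#' For every token position, each token at distance 1..window on either side
#' (within the same document; windows never cross document boundaries)
#' increments the pair count. Underscore-joined multi-word terms occupy a
#' single position, so a joined term is at distance 1 from its neighbour.
#'
#' @param docs a `tagged_corpus`, or a named list of token vectors.
#' @param window symmetrical window size in tokens.
#' @return list of class `cooc_model`: `pairs` (data.table with columns
#'   `term`, `context`, `n`), `term_totals`, `context_totals`,
#'   `grand_total`.
#' @export
cooccurrence_counts <- function(docs, window = 3L) {
  if (inherits(docs, "tagged_corpus")) docs <- docs$documents
  stopifnot(window >= 1L)
  terms_l <- vector("list", 2L * window)
  ctx_l <- vector("list", 2L * window)
  slot <- 0L
  for (k in seq_len(window)) {
    for (d in docs) {
      n <- length(d)
      if (n <= k) next
      a <- d[seq_len(n - k)]
      b <- d[seq.int(k + 1L, n)]
      slot <- slot + 1L
      if (slot > length(terms_l)) {
        terms_l <- c(terms_l, vector("list", length(terms_l)))
        ctx_l <- c(ctx_l, vector("list", length(ctx_l)))
      }
      terms_l[[slot]] <- c(a, b)
      ctx_l[[slot]] <- c(b, a)
    }
  }
  term <- unlist(terms_l, use.names = FALSE)
  context <- unlist(ctx_l, use.names = FALSE)
  if (is.null(term)) term <- context <- character()
  dt <- data.table::data.table(term = term, context = context)
  pairs <- dt[, list(n = .N), by = c("term", "context")]
  data.table::setkeyv(pairs, c("term", "context"))
  tt <- pairs[, list(n = sum(n)), by = "term"]
  ct <- pairs[, list(n = sum(n)), by = "context"]
  structure(list(pairs = pairs,
                 term_totals = stats::setNames(tt$n, tt$term),
                 context_totals = stats::setNames(ct$n, ct$context),
                 grand_total = sum(pairs$n)),
            class = "cooc_model")
}

#' @export
print.cooc_model <- function(x, ...) {
  cat("<cooc_model> ", length(x$term_totals), " terms, ",
      nrow(x$pairs), " nonzero pairs, grand total ", x$grand_total,
      "\n", sep = "")
  invisible(x)
}

# Vectorized Dunning G^2 over parallel 2x2 tables, with optional clipping of
# negative associations (observed co-occurrence below expectation) to zero.
llr_g2 <- function(k11, k12, k21, k22, clip = TRUE) {
  k11 <- as.numeric(k11); k12 <- as.numeric(k12)
  k21 <- as.numeric(k21); k22 <- as.numeric(k22)
  n <- k11 + k12 + k21 + k22
  xlx <- function(k, e) ifelse(k > 0, k * log(k / e), 0)
  e11 <- (k11 + k12) * (k11 + k21) / n
  e12 <- (k11 + k12) * (k12 + k22) / n
  e21 <- (k21 + k22) * (k11 + k21) / n
  e22 <- (k21 + k22) * (k12 + k22) / n
  g2 <- 2 * (xlx(k11, e11) + xlx(k12, e12) + xlx(k21, e21) + xlx(k22, e22))
  g2 <- pmax(g2, 0) # guard tiny negative round-off
  if (clip) g2 <- ifelse(k11 < e11, 0, g2)
  g2
}

#' Log-likelihood ratio association (Dunning G^2)
#'
#' Computes `G^2 = 2 * sum_ij k_ij * ln(k_ij / E_ij)` over the 2x2
#' co-occurrence contingency table, with `E_ij` the expected counts under
#' independence and `0 * ln 0 == 0`. Negative associations (observed joint
#' count below its expectation) are clipped to zero by default, keeping
#' association vectors sparse and attraction-oriented.
#'
#' @param k11 joint count (term with context unit).
#' @param k12 term without the context unit.
#' @param k21 context unit without the term.
#' @param k22 neither.
#' @param clip clip negative associations to 0 (default `TRUE`).
#' @return non-negative numeric (vectorized over the four count arguments).
#' @export
llr <- function(k11, k12, k21, k22, clip = TRUE) {
  if (any(c(k11, k12, k21, k22) < 0)) {
    stop("contingency counts must be non-negative", call. = FALSE)
  }
  n <- k11 + k12 + k21 + k22
  if (any(n <= 0)) stop("all-zero contingency table", call. = FALSE)
  llr_g2(k11, k12, k21, k22, clip = clip)
}

#' Build count-based association vectors
#'
#' Retains the `dim` most frequent context units (by total co-occurrence
#' count, ties broken lexicographically) as dimensions; each vector entry is
#' the log-likelihood ratio of the 2x2 table induced by the pair counts.
#'
#' @param model a `cooc_model`.
#' @param cfg a `dsm_config` (`dim` = retained context units).
#' @param terms terms to vectorize (default: every term in the model).
#' @param clip clip negative associations (see [llr()]).
#' @return a `vector_space` with dimension `min(cfg$dim, #distinct units)`;
#'   column names are the retained context units.
#' @export
build_count_vectors <- function(model, cfg = dsm_config(dim = 150000L),
                                terms = NULL, clip = TRUE) {
  if (length(model$term_totals) == 0L) {
    stop("empty co-occurrence model", call. = FALSE)
  }
  ct <- model$context_totals
  ord <- order(-ct, names(ct), method = "radix")
  d <- min(cfg$dim, length(ct))
  units <- names(ct)[ord][seq_len(d)]
  if (is.null(terms)) terms <- names(model$term_totals)
  terms <- intersect(terms, names(model$term_totals))
  pairs <- model$pairs[model$pairs$term %in% terms &
                         model$pairs$context %in% units, ]
  N <- model$grand_total
  k11 <- pairs$n
  tt <- model$term_totals[pairs$term]
  cc <- model$context_totals[pairs$context]
  val <- llr_g2(k11, tt - k11, cc - k11, N - tt - cc + k11, clip = clip)
  m <- matrix(0, nrow = length(terms), ncol = d,
              dimnames = list(terms, units))
  m[cbind(match(pairs$term, terms), match(pairs$context, units))] <- val
  vector_space(m, provenance = list(model = "count", window = cfg$window,
                                    dim = d, clip = clip))
}
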