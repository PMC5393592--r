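# Cosine ranking of related names and construction of the exportable
# terminological inventory (top-N related names per term, with scores).

#' Cosine similarity
#'
#' @param u,v numeric vectors of equal dimension, both nonzero.
#' @return `u . v / (||u|| ||v||)`, in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector", call. = FALSE)
  s <- sum(u * v) / (nu * nv)
  min(1, max(-1, s))
}

# normalized surface used for self-match exclusion (case/underscore variants)
self_key <- function(x) tolower(gsub("_", " ", x, fixed = TRUE))

#' Rank the most related candidates for a query term
#'
#' Exhaustive cosine scan over the candidate pool, excluding the query
#' itself and any candidate whose surface normalizes to the query's
#' (case/underscore variants). Ties are broken lexicographically so the
#' ranking is deterministic.
#'
#' @param query term present in `space`.
#' @param space a `vector_space`.
#' @param pool candidate terms (default: all terms of the space).
#' @param n number of candidates to return.
#' @return a `ranked_candidates`: list with `query` and `candidates`
#'   (data.frame with columns `term`, `score`, non-increasing scores).
#' @export
top_n <- function(query, space, pool = NULL, n = 20L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  vocab <- rownames(space$vectors)
  if (!query %in% vocab) stop("query term not in vector space: ", query,
                              call. = FALSE)
  if (is.null(pool)) pool <- vocab
  pool <- intersect(pool, vocab)
  pool <- pool[self_key(pool) != self_key(query)]
  if (length(pool) == 0L) {
    return(ranked_candidates(query, character(), numeric()))
  }
  q <- space$vectors[query, ]
  m <- space$vectors[pool, , drop = FALSE]
  nq <- sqrt(sum(q^2))
  nm <- sqrt(rowSums(m^2))
  if (nq == 0) stop("query has a zero vector: ", query, call. = FALSE)
  ok <- nm > 0
  pool <- pool[ok]
  scores <- as.numeric(m[ok, , drop = FALSE] %*% q) / (nm[ok] * nq)
  scores <- pmin(1, pmax(-1, scores))
  ord <- order(-scores, pool, method = "radix")
  keep <- ord[seq_len(min(n, length(ord)))]
  ranked_candidates(query, pool[keep], scores[keep])
}

#' Construct a ranked-candidates object
#' @param query query term.
#' @param terms candidate terms in rank order.
#' @param scores their similarity scores (non-increasing).
#' @return list of class `ranked_candidates`.
#' @export
ranked_candidates <- function(query, terms, scores) {
  if (length(terms) != length(scores)) stop("terms/scores length mismatch",
                                            call. = FALSE)
  if (anyDuplicated(terms)) stop("duplicate candidate terms", call. = FALSE)
  if (length(scores) > 1L && any(diff(scores) > 1e-12)) {
    stop("candidate scores must be non-increasing", call. = FALSE)
  }
  structure(list(query = query,
                 candidates = data.frame(term = as.character(terms),
                                         score = as.numeric(scores),
                                         stringsAsFactors = FALSE)),
            class = "ranked_candidates")
}

#' @export
print.ranked_candidates <- function(x, ...) {
  cat("<ranked_candidates> query:", x$query, "\n")
  print(utils::head(x$candidates, 10L))
  invisible(x)
}

#' Build a terminological inventory
#'
#' One entry per term passing the frequency filter: the term, its corpus
#' frequency, and its top-N most related names by cosine similarity. The
#' candidate pool is the set of dictionary terms present in the space (not
#' the full vocabulary), matching the intended use: ranking species names
#' against species names. Entries are ordered lexicographically by term.
#'
#' @param space a `vector_space`.
#' @param freqs named vector of term corpus frequencies.
#' @param min_freq minimum frequency for a term to be included (default 5,
#'   the threshold used for the published inventory).
#' @param n related names per entry (default 20).
#' @param pool candidate terms (default: names of `freqs` present in the
#'   space, i.e. dictionary terms).
#' @return list of class `term_inventory`; each element has `term`,
#'   `frequency`, `related` (data.frame `term`, `score`).
#' @export
build_inventory <- function(space, freqs, min_freq = 5L, n = 20L, pool = NULL) {
  if (nrow(space$vectors) == 0L) stop("empty vector space", call. = FALSE)
  if (min_freq < 1L) stop("min_freq must be >= 1", call. = FALSE)
  if (is.null(pool)) pool <- intersect(names(freqs), rownames(space$vectors))
  terms <- sort(intersect(select_terms(freqs, min_freq), rownames(space$vectors)),
                method = "radix")
  entries <- lapply(terms, function(tm) {
    rc <- top_n(tm, space, pool = pool, n = n)
    list(term = tm, frequency = as.integer(freqs[[tm]]),
         related = rc$candidates)
  })
  names(entries) <- terms
  structure(entries, class = "term_inventory")
}

#' @export
print.term_inventory <- function(x, ...) {
  cat("<term_inventory> ", length(x), " terms\n", sep = "")
  for (e in utils::head(x, 3L)) {
    cat("  ", e$term, " (freq ", e$frequency, "): ",
        paste(utils::head(e$related$term, 3L), collapse = ", "),
        if (nrow(e$related) > 3L) ", ...", "\n", sep = "")
  }
  invisible(x)
}

#' Write an inventory as TSV
#'
#' One row per related name: `term<TAB>frequency<TAB>rank<TAB>related_term
#' <TAB>cosine`. Scores are printed with 6 decimals; regeneration from the
#' same vector file is byte-identical.
#'
#' @param inv a `term_inventory`.
#' @param path output file.
#' @export
write_inventory <- function(inv, path) {
  rows <- character()
  for (e in inv) {
    if (nrow(e$related) == 0L) next
    rows <- c(rows, paste(e$term, e$frequency, seq_len(nrow(e$related)),
                          e$related$term, sprintf("%.6f", e$related$score),
                          sep = "\t"))
  }
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}
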