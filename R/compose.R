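# Basic additive model (BAM): the vector of a multi-word term is the sum of
# the L2-normalized vectors of its component words. The sum is deliberately
# not re-normalized: cosine ranking is scale-invariant, and the model is the
# plain sum of unit vectors.

#' Compose component vectors additively
#'
#' Returns `sum_i v(w_i) / ||v(w_i)||_2`. With a single component this
#' reduces to unit normalization; component order never matters.
#'
#' @param component_vectors numeric matrix (one row per component) or list of
#'   equal-length numeric vectors.
#' @return numeric vector of the same dimension.
#' @export
bam_compose <- function(component_vectors) {
  if (is.list(component_vectors)) {
    dims <- unique(lengths(component_vectors))
    if (length(dims) != 1L) stop("component dimension mismatch", call. = FALSE)
    component_vectors <- do.call(rbind, component_vectors)
  }
  if (!is.matrix(component_vectors) || nrow(component_vectors) < 1L) {
    stop("need at least one component vector", call. = FALSE)
  }
  nrm <- sqrt(rowSums(component_vectors^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0L) {
    stop("zero-norm component vector at position ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  colSums(component_vectors / nrm)
}

#' Compose a multi-word term space from a single-word base space
#'
#' For each term, splits its underscore-joined surface into component words,
#' looks the components up in the base space, and combines them with
#' [bam_compose()]. Terms with any out-of-vocabulary or zero-norm component
#' are excluded (a message reports how many).
#'
#' @param base a `vector_space` of single-word vectors.
#' @param terms character vector of term surfaces (underscore-joined
#'   multi-word terms; plain names with spaces are accepted too).
#' @return a `vector_space` over the composable terms; provenance model is
#'   the base model name with a `-BAM` suffix.
#' @export
compose_space <- function(base, terms) {
  terms <- unique(terms)
  vocab <- rownames(base$vectors)
  nrm <- sqrt(rowSums(base$vectors^2))
  rows <- vector("list", length(terms))
  kept <- logical(length(terms))
  for (i in seq_along(terms)) {
    comps <- if (grepl("_", terms[[i]], fixed = TRUE)) {
      split_term(terms[[i]])
    } else {
      tokenize_text(terms[[i]])
    }
    if (length(comps) == 0L) next
    if (!all(comps %in% vocab)) next
    if (any(nrm[comps] == 0)) next
    rows[[i]] <- bam_compose(base$vectors[comps, , drop = FALSE])
    kept[[i]] <- TRUE
  }
  n_excluded <- sum(!kept)
  if (n_excluded > 0L) {
    message(n_excluded, " of ", length(terms),
            " terms excluded from composition (missing or zero-norm components)")
  }
  m <- do.call(rbind, rows[kept])
  if (is.null(m)) m <- matrix(numeric(), 0L, ncol(base$vectors))
  rownames(m) <- terms[kept]
  prov <- base$provenance
  prov$model <- paste0(if (is.null(prov$model)) "base" else prov$model, "-BAM")
  prov$n_excluded <- n_excluded
  vector_space(m, provenance = prov)
}
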