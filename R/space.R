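#' Vector space of term representations
#'
#' A thin container around a numeric matrix with one row per term. Provenance
#' records how the space was built (model type, window, dimension, seed) so
#' downstream artifacts can be stamped.
#'
#' @param vectors numeric matrix with rownames = terms.
#' @param provenance named list describing the model.
#' @return object of class `vector_space`.
#' @export
vector_space <- function(vectors, provenance = list()) {
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    stop("vectors must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(vectors)) && nrow(vectors) > 0L) {
    stop("vector matrix must carry terms as rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(vectors))) {
    stop("duplicate terms in vector space", call. = FALSE)
  }
  if (nrow(vectors) > 0L && any(!is.finite(vectors))) {
    stop("vector space contains non-finite entries", call. = FALSE)
  }
  structure(list(vectors = vectors, provenance = provenance),
            class = "vector_space")
}

#' @export
print.vector_space <- function(x, ...) {
  p <- x$provenance
  cat("<vector_space> ", nrow(x$vectors), " terms x ", ncol(x$vectors),
      " dims", if (!is.null(p$model)) paste0(" [", p$model, "]"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.vector_space <- function(x) dim(x$vectors)

#' Terms of a vector space
#' @param space a `vector_space`.
#' @return character vector.
#' @export
space_terms <- function(space) rownames(space$vectors)

#' Look up term vectors
#' @param space a `vector_space`.
#' @param terms character vector; all must be present.
#' @return numeric matrix (rows in request order).
#' @export
space_vectors <- function(space, terms) {
  miss <- setdiff(terms, rownames(space$vectors))
  if (length(miss) > 0L) {
    stop("terms not in vector space: ", paste(utils::head(miss, 5L), collapse = ", "),
         call. = FALSE)
  }
  space$vectors[terms, , drop = FALSE]
}

#' Restrict a vector space to a subset of terms
#' @param space a `vector_space`.
#' @param terms terms to keep (silently dropping absent ones).
#' @return a `vector_space`.
#' @export
space_subset <- function(space, terms) {
  keep <- intersect(terms, rownames(space$vectors))
  vector_space(space$vectors[keep, , drop = FALSE], space$provenance)
}
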