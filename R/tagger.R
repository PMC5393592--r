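# Dictionary term tagging: locate dictionary names in token streams and
# rewrite multi-word names as single underscore-joined tokens.
#
# Matching policy: scientific names are matched case-sensitively on the genus
# initial and case-insensitively elsewhere (binomial convention: the generic
# name always carries an uppercase initial); vernacular and unlabelled names
# are matched fully case-insensitively. A matched span is replaced by the
# dictionary entry's canonical underscore-joined surface, which also collapses
# case variants onto one countable term.

escape_underscores <- function(x) gsub("_", "\\_", x, fixed = TRUE)
unescape_underscores <- function(x) gsub("\\_", "_", x, fixed = TRUE)

#' Join name components into a single tagged token
#' @param components character vector of component words.
#' @return underscore-joined token (pre-existing underscores escaped).
#' @export
join_term <- function(components) {
  paste(escape_underscores(components), collapse = "_")
}

#' Split a tagged token back into its component words
#' @param term underscore-joined token.
#' @return character vector of components.
#' @export
split_term <- function(term) {
  unescape_underscores(strsplit(term, "(?<!\\\\)_", perl = TRUE)[[1L]])
}

#' Underscore-joined surface of a dictionary name
#' @param name name string (components separated by spaces).
#' @return canonical joined token.
#' @export
term_surface <- function(name) join_term(tokenize_text(name))

# case-policy keys over a component sequence: the genus initial (first
# character of the first component) is case-sensitive, all else lowercased
sci_key <- function(toks) {
  out <- tolower(toks)
  substr(out[1L], 1L, 1L) <- substr(toks[1L], 1L, 1L)
  out
}
vern_key <- function(tok) tolower(tok)

#' Build a matching index over a term dictionary
#'
#' @param dict a `term_dictionary`.
#' @param max_len maximum entry length in tokens (longer entries are dropped
#'   with a warning); binomials, trinomials and vernaculars fit comfortably.
#' @return opaque index used by [tag_terms()].
#' @export
build_dict_index <- function(dict, max_len = 6L) {
  env_s <- new.env(parent = emptyenv())
  env_v <- new.env(parent = emptyenv())
  # first-component key -> integer vector of candidate span lengths (desc)
  len_s <- new.env(parent = emptyenv())
  len_v <- new.env(parent = emptyenv())
  n_long <- 0L
  add <- function(env, lenv, key_comps, surface) {
    key <- paste(key_comps, collapse = " ")
    assign(key, surface, envir = env)
    first <- key_comps[[1L]]
    lens <- unique(c(get0(first, envir = lenv, ifnotfound = integer()),
                     length(key_comps)))
    assign(first, sort(lens, decreasing = TRUE), envir = lenv)
  }
  for (i in seq_len(nrow(dict))) {
    comps <- tokenize_text(dict$name[[i]])
    if (length(comps) == 0L) next
    if (length(comps) > max_len) { n_long <- n_long + 1L; next }
    surface <- join_term(comps)
    if (dict$kind[[i]] == "scientific") {
      add(env_s, len_s, sci_key(comps), surface)
      # the canonical joined surface maps to itself (idempotent re-tagging)
      add(env_s, len_s, sci_key(surface), surface)
    } else {
      add(env_v, len_v, vern_key(comps), surface)
      add(env_v, len_v, vern_key(surface), surface)
    }
  }
  if (n_long > 0L) {
    warning(n_long, " dictionary entries longer than ", max_len,
            " tokens were ignored", call. = FALSE)
  }
  structure(list(env_s = env_s, env_v = env_v, len_s = len_s, len_v = len_v,
                 max_len = max_len),
            class = "dict_index")
}

#' Tag dictionary terms in one document
#'
#' Greedy left-to-right longest-match scan: at each position the longest
#' matching dictionary entry wins, the matched span is replaced by one
#' underscore-joined token, and scanning resumes after it. Matches never
#' overlap and never cross document boundaries.
#'
#' @param tokens character vector of document tokens.
#' @param index a `dict_index` from [build_dict_index()] (or a
#'   `term_dictionary`, indexed on the fly).
#' @return character vector with matched spans joined.
#' @export
tag_terms <- function(tokens, index) {
  if (inherits(index, "term_dictionary")) index <- build_dict_index(index)
  n <- length(tokens)
  if (n == 0L) return(tokens)
  # per-token keys: initial-preserving (genus position) and fully lowercased
  sk <- paste0(substr(tokens, 1L, 1L), tolower(substring(tokens, 2L)))
  vk <- vern_key(tokens)
  out <- character(n)
  n_out <- 0L
  i <- 1L
  while (i <= n) {
    surface <- NULL
    lens <- unique(c(get0(sk[[i]], envir = index$len_s, ifnotfound = integer()),
                     get0(vk[[i]], envir = index$len_v, ifnotfound = integer())))
    if (length(lens) > 0L) {
      for (L in sort(lens, decreasing = TRUE)) {
        if (i + L - 1L > n) next
        span <- i:(i + L - 1L)
        skey <- if (L == 1L) sk[[i]] else
          paste(c(sk[[i]], vk[span[-1L]]), collapse = " ")
        hit <- get0(skey, envir = index$env_s, ifnotfound = NULL)
        if (is.null(hit)) {
          hit <- get0(paste(vk[span], collapse = " "), envir = index$env_v,
                      ifnotfound = NULL)
        }
        if (!is.null(hit)) { surface <- hit; i <- i + L; break }
      }
    }
    if (is.null(surface)) { surface <- tokens[[i]]; i <- i + 1L }
    n_out <- n_out + 1L
    out[[n_out]] <- surface
  }
  out[seq_len(n_out)]
}

#' Tag a whole corpus and count term occurrences
#'
#' @param corpus named list of token vectors.
#' @param dict a `term_dictionary`.
#' @param max_len maximum entry length passed to [build_dict_index()].
#' @return a `tagged_corpus`: list with `documents` (tagged token vectors),
#'   `term_counts` (named integer vector over dictionary terms present),
#'   `terms` (all canonical dictionary surfaces).
#' @export
tag_corpus <- function(corpus, dict, max_len = 6L) {
  index <- build_dict_index(dict, max_len = max_len)
  docs <- lapply(corpus, tag_terms, index = index)
  surfaces <- unique(vapply(dict$name, term_surface, "", USE.NAMES = FALSE))
  all_tokens <- unlist(docs, use.names = FALSE)
  hits <- all_tokens[all_tokens %in% surfaces]
  counts <- table(hits)
  tc <- stats::setNames(as.integer(counts), names(counts))
  structure(list(documents = docs, term_counts = tc, terms = surfaces),
            class = "tagged_corpus")
}

#' @export
print.tagged_corpus <- function(x, ...) {
  cat("<tagged_corpus> ", length(x$documents), " documents, ",
      length(x$term_counts), " dictionary terms observed (",
      sum(x$term_counts), " occurrences)\n", sep = "")
  invisible(x)
}

#' Term occurrence frequencies of a tagged corpus
#'
#' @param tagged a `tagged_corpus`.
#' @return named integer vector of exact occurrence counts of dictionary
#'   terms (canonical joined surfaces); absent terms are simply not present.
#' @export
term_frequencies <- function(tagged) {
  stopifnot(inherits(tagged, "tagged_corpus"))
  tagged$term_counts
}

#' Select terms meeting a frequency threshold
#'
#' @param freqs named numeric/integer vector of term frequencies.
#' @param min_freq inclusive threshold (`>= min_freq`), at least 1.
#' @return character vector of retained terms.
#' @export
select_terms <- function(freqs, min_freq) {
  if (!is.numeric(min_freq) || length(min_freq) != 1L || min_freq < 1) {
    stop("min_freq must be a single value >= 1", call. = FALSE)
  }
  names(freqs)[freqs >= min_freq]
}
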