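#' Tokenize a text string
#'
#' Splits on Unicode whitespace and strips leading/trailing punctuation from
#' each token; internal hyphens and underscores are preserved. This is robust
#' on noisy (OCR-like) text and keeps multi-word name components recoverable.
#'
#' @param x character vector of text (each element tokenized independently,
#'   results concatenated).
#' @return character vector of tokens (no empty strings).
#' @examples
#' tokenize_text("Panthera leo roams.")
#' @export
tokenize_text <- function(x) {
  toks <- unlist(strsplit(x, "[[:space:]]+"), use.names = FALSE)
  toks <- gsub("^[[:punct:]]+", "", toks)
  # strip trailing punctuation but keep a trailing underscore escape intact
  toks <- gsub("[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Read a corpus of documents
#'
#' Reads either a directory of UTF-8 `.txt` files (one document per file) or a
#' single file with one document per non-empty line. Order is deterministic:
#' lexicographic by file name, then line number.
#'
#' @param path directory (mode `"dir"`) or file (mode `"line"`).
#' @param mode `"dir"` or `"line"`.
#' @return named list of character token vectors; names are document ids
#'   (file names, or `"<basename>:<line>"` in line mode).
#' @export
read_corpus <- function(path, mode = c("dir", "line")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    stop("corpus path does not exist: ", path, call. = FALSE)
  }
  docs <- list()
  if (mode == "dir") {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    for (f in files) {
      lines <- tryCatch(readLines(f, encoding = "UTF-8", warn = FALSE),
                        error = function(e) NULL)
      if (is.null(lines)) {
        warning("skipping undecodable document: ", f, call. = FALSE)
        next
      }
      docs[[basename(f)]] <- tokenize_text(lines)
    }
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    nm <- paste0(basename(path), ":", keep)
    docs <- lapply(lines[keep], tokenize_text)
    names(docs) <- nm
  }
  docs
}

#' Write a corpus as a line-per-document file
#'
#' @param corpus named list of token vectors.
#' @param path output file.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, paste, "", collapse = " "), path, useBytes = TRUE)
  invisible(path)
}

#' Load a term dictionary
#'
#' One name per line; an optional second TAB-separated column labels the entry
#' kind (`scientific`, `vernacular` or `unknown`). Duplicate names collapse to
#' one entry (the first kind seen wins).
#'
#' @param path plain-text file.
#' @return a `term_dictionary`: data.frame with columns `name` and `kind`.
#' @export
load_dictionary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("dictionary file has no entries: ", path, call. = FALSE)
    return(term_dictionary(character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  name <- trimws(vapply(parts, `[[`, "", 1L))
  kind <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[[2L]]) else "unknown", "")
  keep <- !duplicated(name) & nzchar(name)
  message(sum(keep), " dictionary entries loaded from ", path)
  term_dictionary(name[keep], kind[keep])
}

#' Construct a term dictionary from character vectors
#'
#' @param name character vector of names (may contain spaces).
#' @param kind per-entry label in `scientific`, `vernacular`, `unknown`.
#' @return data.frame of class `term_dictionary`.
#' @export
term_dictionary <- function(name, kind = "unknown") {
  kind <- rep_len(kind, length(name))
  bad <- !kind %in% c("scientific", "vernacular", "unknown")
  if (any(bad)) stop("unknown name kind: ", paste(unique(kind[bad]), collapse = ", "),
                     call. = FALSE)
  d <- data.frame(name = as.character(name), kind = kind,
                  stringsAsFactors = FALSE)
  d <- d[!duplicated(d$name) & nzchar(d$name), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("term_dictionary", "data.frame")
  d
}

#' Load a reference standard of preferred names and semantic variants
#'
#' TSV rows of the form `preferred<TAB>variant1|variant2|...`. Every preferred
#' name must map to at least one variant; a variant may legitimately recur
#' under several preferred names (vernacular polysemy, e.g. "velvetleaf").
#'
#' @param path TSV file.
#' @return a `reference_standard`: named list mapping preferred name to a
#'   character vector of variants.
#' @export
load_reference_standard <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  recs <- list()
  for (i in keep) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    pref <- if (length(parts) >= 1L) trimws(parts[[1L]]) else ""
    vars <- if (length(parts) >= 2L) {
      v <- trimws(strsplit(parts[[2L]], "|", fixed = TRUE)[[1L]])
      v[nzchar(v)]
    } else character()
    if (!nzchar(pref) || length(vars) == 0L) {
      stop("reference-standard row with no variants at line ", i, ": ",
           lines[[i]], call. = FALSE)
    }
    recs[[pref]] <- unique(c(recs[[pref]], vars))
  }
  structure(recs, class = "reference_standard")
}

#' Write a reference standard to TSV
#'
#' @param rs a `reference_standard`.
#' @param path output file.
#' @export
write_reference_standard <- function(rs, path) {
  writeLines(paste0(names(rs), "\t",
                    vapply(rs, paste, "", collapse = "|")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Summarise a reference standard
#'
#' Reports the counts used to characterise reference-standard data sets:
#' number of preferred names, number of variants, total distinct name slots
#' and the average number of variants per preferred name.
#'
#' @param rs a `reference_standard`.
#' @return list with `n_preferred`, `n_variants`, `total_names`,
#'   `avg_variants` (rounded to 2 decimals, as conventionally reported).
#' @export
reference_standard_summary <- function(rs) {
  np <- length(rs)
  nv <- sum(lengths(rs))
  list(n_preferred = np, n_variants = nv, total_names = np + nv,
       avg_variants = round(nv / np, 2))
}

#' Component-sharing structure of a reference standard
#'
#' For binomial-style names, counts how often semantic variants share a
#' component word with their preferred name: variants sharing the genus
#' (first component), variants sharing the specific epithet (second
#' component, matched against either component of the variant), and preferred
#' names with at least one component-sharing variant. Comparison is
#' case-insensitive.
#'
#' @param rs a `reference_standard`.
#' @return list with `n_preferred_shared`, `n_shared_genus`,
#'   `n_shared_epithet`, `pct_preferred_shared` (percentage of preferred
#'   names with a shared component).
#' @export
shared_component_summary <- function(rs) {
  n_pref_shared <- 0L; n_genus <- 0L; n_epi <- 0L
  for (pref in names(rs)) {
    pc <- tolower(strsplit(pref, " ", fixed = TRUE)[[1L]])
    any_shared <- FALSE
    for (v in rs[[pref]]) {
      vc <- tolower(strsplit(v, " ", fixed = TRUE)[[1L]])
      if (length(pc) < 2L || length(vc) < 2L) next
      if (vc[[1L]] == pc[[1L]]) n_genus <- n_genus + 1L
      if (pc[[2L]] %in% vc) n_epi <- n_epi + 1L
      if (length(intersect(pc, vc)) > 0L) any_shared <- TRUE
    }
    if (any_shared) n_pref_shared <- n_pref_shared + 1L
  }
  list(n_preferred_shared = n_pref_shared,
       n_shared_genus = n_genus,
       n_shared_epithet = n_epi,
       pct_preferred_shared = 100 * n_pref_shared / length(rs))
}

#' Normalization configuration
#'
#' @param lowercase_context lowercase context tokens (dictionary terms are
#'   always exempt).
#' @param stopwords character vector of stop words to remove, or `NULL`.
#'   `english_stopwords()` supplies the shipped default list.
#' @param lemmatize apply the light rule-based English lemmatizer
#'   (plural and inflectional suffix stripping).
#' @return list of class `norm_config`.
#' @export
norm_config <- function(lowercase_context = TRUE,
                        stopwords = english_stopwords(),
                        lemmatize = FALSE) {
  structure(list(lowercase_context = isTRUE(lowercase_context),
                 stopwords = unique(as.character(stopwords)),
                 lemmatize = isTRUE(lemmatize)),
            class = "norm_config")
}

#' Shipped English stop-word list
#'
#' A fixed, deterministic function-word list (articles, prepositions,
#' pronouns, auxiliaries and common adverbs).
#'
#' @return character vector.
#' @export
english_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "also", "am",
    "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "could", "did",
    "do", "does", "doing", "down", "during", "each", "few", "for", "from",
    "further", "had", "has", "have", "having", "he", "her", "here", "hers",
    "him", "his", "how", "i", "if", "in", "into", "is", "it", "its", "itself",
    "just", "may", "me", "might", "more", "most", "must", "my", "no", "nor",
    "not", "now", "of", "off", "on", "once", "only", "or", "other", "our",
    "ours", "out", "over", "own", "same", "shall", "she", "should", "so",
    "some", "such", "than", "that", "the", "their", "theirs", "them", "then",
    "there", "these", "they", "this", "those", "through", "to", "too", "under",
    "until", "up", "upon", "very", "was", "we", "were", "what", "when",
    "where", "which", "while", "who", "whom", "why", "will", "with", "would",
    "you", "your", "yours")
}

# Light rule-based lemmatizer: regular plurals and a few inflections.
# Deliberately conservative; never applied to dictionary terms.
lemmatize_token <- function(tok) {
  n <- nchar(tok)
  if (n > 3L && grepl("ies$", tok)) return(sub("ies$", "y", tok))
  if (n > 4L && grepl("(ches|shes|xes|sses|zes)$", tok)) return(sub("es$", "", tok))
  if (n > 3L && grepl("[^su]s$", tok)) return(sub("s$", "", tok))
  tok
}

#' Normalize the context tokens of a document
#'
#' Applies lowercasing, stop-word removal and light lemmatization to context
#' tokens. Tokens that exactly match a protected term (dictionary entries,
#' including underscore-joined multi-word tokens) are passed through
#' unchanged so they survive to be vectorized.
#'
#' @param tokens character vector of document tokens.
#' @param cfg a `norm_config`.
#' @param protect character vector of protected tokens (e.g. tagged terms).
#' @return normalized character vector.
#' @export
normalize_tokens <- function(tokens, cfg = norm_config(), protect = character()) {
  if (length(tokens) == 0L) return(tokens)
  prot <- tokens %in% protect
  out <- tokens
  ctx <- out[!prot]
  if (cfg$lowercase_context) ctx <- tolower(ctx)
  if (cfg$lemmatize) ctx <- vapply(ctx, lemmatize_token, "", USE.NAMES = FALSE)
  out[!prot] <- ctx
  if (length(cfg$stopwords) > 0L) {
    drop <- !prot & tolower(out) %in% cfg$stopwords
    out <- out[!drop]
  }
  out
}

#' Normalize every document of a corpus
#'
#' @inheritParams normalize_tokens
#' @param corpus named list of token vectors.
#' @return corpus with normalized documents.
#' @export
normalize_corpus <- function(corpus, cfg = norm_config(), protect = character()) {
  lapply(corpus, normalize_tokens, cfg = cfg, protect = protect)
}

#' Write a vector space in word2vec text format
#'
#' Header line `"<term_count> <dimension>"`, then one row per term:
#' `term v1 ... vD`, values at full precision (at least 8 significant
#' digits). Multi-word terms are written in their underscore-joined form.
#'
#' @param space a `vector_space`.
#' @param path output file.
#' @export
write_vectors <- function(space, path) {
  m <- space$vectors
  if (is.null(m) || nrow(m) == 0L) {
    stop("refusing to write an empty vector space", call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i], paste(formatC(m[i, ], format = "g", digits = 10),
                                collapse = " "))
  }, "")
  writeLines(rows, con)
  invisible(path)
}

#' Read a vector space from word2vec text format
#'
#' @param path file written by [write_vectors()] (or any word2vec-style text
#'   vector file).
#' @return a `vector_space`.
#' @export
read_vectors <- function(path) {
  con <- file(path, open = "rt", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- scan(con, what = integer(), n = 2L, quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed vector file header", call. = FALSE)
  v <- hdr[[1L]]; d <- hdr[[2L]]
  m <- matrix(0, nrow = v, ncol = d)
  terms <- character(v)
  for (i in seq_len(v)) {
    ln <- readLines(con, n = 1L)
    parts <- strsplit(ln, " ", fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != d + 1L) {
      stop("vector row for term '", parts[1L], "' has ", length(parts) - 1L,
           " values, expected ", d, call. = FALSE)
    }
    terms[[i]] <- parts[[1L]]
    m[i, ] <- as.numeric(parts[-1L])
  }
  rownames(m) <- terms
  vector_space(m, provenance = list(model = "file", source = path))
}
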