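# Ranked-retrieval evaluation against reference standards: top-N accuracy,
# precision@N, recall@N (N = 1..20) and mean average precision.
#
# Name comparison normalizes surfaces to a common key (spaces to
# underscores, case-insensitive) so that gold variants written as plain
# names match tagged underscore-joined candidates.

canon_term <- function(x) tolower(gsub(" ", "_", x, fixed = TRUE))

#' Top-N accuracy over a set of ranked queries
#'
#' The ratio between the number of query terms whose top-N ranked candidates
#' include at least one correct semantic variant, and the total number of
#' queries.
#'
#' @param rankings list of `ranked_candidates`.
#' @param gold a `reference_standard`; every query must appear in it.
#' @param n cutoff.
#' @return numeric in `[0, 1]`.
#' @export
top_n_accuracy <- function(rankings, gold, n) {
  if (length(rankings) == 0L) stop("no rankings supplied", call. = FALSE)
  gold_keys <- stats::setNames(lapply(gold, canon_term), canon_term(names(gold)))
  hits <- vapply(rankings, function(rc) {
    gk <- gold_keys[[canon_term(rc$query)]]
    if (is.null(gk)) stop("query missing from reference standard: ", rc$query,
                          call. = FALSE)
    top <- canon_term(utils::head(rc$candidates$term, n))
    any(top %in% gk)
  }, logical(1L))
  mean(hits)
}

#' Precision and recall at N for one ranked query
#'
#' `precision = |top-N intersect gold| / N`; `recall = |top-N intersect
#' gold| / |gold|`.
#'
#' @param ranking a `ranked_candidates`.
#' @param gold_variants character vector of correct variants (non-empty).
#' @param n cutoff (`>= 1`).
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall_at_n <- function(ranking, gold_variants, n) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  gk <- unique(canon_term(gold_variants))
  if (length(gk) == 0L) stop("empty gold variant set", call. = FALSE)
  top <- canon_term(utils::head(ranking$candidates$term, n))
  tp <- sum(top %in% gk)
  c(precision = tp / n, recall = tp / length(gk))
}

#' Average precision of one ranked query
#'
#' `AP = (1/|gold|) * sum over correctly retrieved variants of
#' precision at the variant's rank`, over the full ranking. Gold variants
#' never retrieved contribute zero.
#'
#' @inheritParams precision_recall_at_n
#' @return numeric in `[0, 1]`.
#' @export
average_precision <- function(ranking, gold_variants) {
  gk <- unique(canon_term(gold_variants))
  if (length(gk) == 0L) stop("empty gold variant set", call. = FALSE)
  cand <- canon_term(ranking$candidates$term)
  rel <- cand %in% gk
  if (!any(rel)) return(0)
  ranks <- which(rel)
  sum(seq_along(ranks) / ranks) / length(gk)
}

#' Evaluate a model's rankings against a reference standard
#'
#' Computes top-N accuracy and mean precision/recall at every N of
#' `n_range`, plus MAP (mean of per-query average precision). Recall and AP
#' denominators count only gold variants present in the candidate vocabulary
#' (`vocab`) when one is given — variants the model can never retrieve are
#' excluded from the denominator — while the unrestricted variant counts are
#' also recorded so both conventions stay computable. Queries whose gold set
#' is empty after restriction are excluded and counted.
#'
#' @param rankings list of `ranked_candidates`.
#' @param gold a `reference_standard`.
#' @param n_range cutoffs (default `1:20`).
#' @param vocab candidate vocabulary for gold restriction, or `NULL` for no
#'   restriction.
#' @param model_id label recorded in the report.
#' @return list of class `eval_report`: `per_n` (data.frame `n`,
#'   `accuracy`, `precision`, `recall`), `map`, `ap` (per-query),
#'   `n_queries`, `n_excluded`, `n_gold_in_vocab`, `n_gold_total`.
#' @export
evaluate_model <- function(rankings, gold, n_range = 1:20, vocab = NULL,
                           model_id = "model") {
  if (length(rankings) == 0L) stop("no rankings supplied", call. = FALSE)
  gold_keys <- stats::setNames(lapply(gold, canon_term), canon_term(names(gold)))
  vkeys <- if (is.null(vocab)) NULL else canon_term(vocab)

  n_gold_total <- 0L; n_gold_in_vocab <- 0L
  kept <- list(); excluded <- character()
  for (rc in rankings) {
    gk <- gold_keys[[canon_term(rc$query)]]
    if (is.null(gk)) stop("query missing from reference standard: ", rc$query,
                          call. = FALSE)
    n_gold_total <- n_gold_total + length(gk)
    if (!is.null(vkeys)) gk <- intersect(gk, vkeys)
    n_gold_in_vocab <- n_gold_in_vocab + length(gk)
    if (length(gk) == 0L) { excluded <- c(excluded, rc$query); next }
    kept[[length(kept) + 1L]] <- list(rc = rc, gold = gk)
  }
  if (length(kept) == 0L) stop("no queries with in-vocabulary gold variants",
                               call. = FALSE)

  per_n <- do.call(rbind, lapply(n_range, function(n) {
    pr <- vapply(kept, function(k)
      precision_recall_at_n(k$rc, k$gold, n), numeric(2L))
    acc <- mean(vapply(kept, function(k) {
      any(canon_term(utils::head(k$rc$candidates$term, n)) %in% k$gold)
    }, logical(1L)))
    data.frame(n = n, accuracy = acc, precision = mean(pr["precision", ]),
               recall = mean(pr["recall", ]))
  }))
  ap <- vapply(kept, function(k) average_precision(k$rc, k$gold), numeric(1L))
  names(ap) <- vapply(kept, function(k) k$rc$query, "")
  structure(list(model_id = model_id, per_n = per_n, map = mean(ap), ap = ap,
                 n_queries = length(kept), n_excluded = length(excluded),
                 excluded = excluded, n_gold_in_vocab = n_gold_in_vocab,
                 n_gold_total = n_gold_total),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$model_id, ": ", x$n_queries, " queries, MAP = ",
      sprintf("%.4f", x$map), "\n", sep = "")
  print(x$per_n[x$per_n$n %in% c(1L, 5L, 10L, 20L), ], row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' Rows `(model, N, accuracy, precision, recall)` followed by a MAP summary
#' row; per-query average precision goes to a companion file so external
#' statistics packages can run model-comparison tests on it.
#'
#' @param report an `eval_report`.
#' @param path output TSV.
#' @param ap_path optional output TSV of per-query AP (`query<TAB>ap`).
#' @export
write_eval_report <- function(report, path, ap_path = NULL) {
  hdr <- "model\tN\taccuracy\tprecision\trecall"
  rows <- sprintf("%s\t%d\t%.6f\t%.6f\t%.6f", report$model_id,
                  report$per_n$n, report$per_n$accuracy,
                  report$per_n$precision, report$per_n$recall)
  map_row <- sprintf("%s\tMAP\t%.6f\t\t", report$model_id, report$map)
  writeLines(c(hdr, rows, map_row), path, useBytes = TRUE)
  if (!is.null(ap_path)) {
    writeLines(c("query\tap",
                 sprintf("%s\t%.6f", names(report$ap), report$ap)),
               ap_path, useBytes = TRUE)
  }
  invisible(path)
}
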