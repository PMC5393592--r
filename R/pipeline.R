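# End-to-end pipeline: tag -> normalize -> train (-> compose) -> rank ->
# inventory (-> evaluate), with every artifact stamped by a config hash so
# reruns are verifiably reproducible.

pipeline_defaults <- function() {
  list(corpus = NULL, corpus_mode = "line", dict = NULL, gold = NULL,
       out = NULL, method = "count", compose = FALSE, window = 3L,
       dim = NULL, min_count = 5L, min_freq = 5L, top_n = 20L, seed = 1L,
       epochs = NULL, log_level = "info")
}

#' Load a pipeline run configuration
#'
#' Flat key-value YAML; unknown keys are rejected, missing keys take
#' defaults (`method` "count", `window` 3, `min_freq` 5, `top_n` 20,
#' `seed` 1; `dim` defaults to 150000 for the count model and 300 for the
#' prediction-based ones).
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file.
#' @return named list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  file_cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (src in list(file_cfg, overrides)) {
    bad <- setdiff(names(src), names(cfg))
    if (length(bad) > 0L) stop("unknown config keys: ",
                               paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(src)] <- src
  }
  if (!cfg$method %in% c("count", "cbow", "glove")) {
    stop("method must be count, cbow or glove", call. = FALSE)
  }
  if (is.null(cfg$dim)) cfg$dim <- if (cfg$method == "count") 150000L else 300L
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(cfg[order(names(cfg))], f)
  unname(tools::md5sum(f))
}

#' Run the full inventory-construction pipeline
#'
#' Executes tag -> normalize -> train (-> compose when the model is a BAM
#' variant) -> rank -> inventory, and evaluate when a reference standard is
#' supplied. Artifacts written under `cfg$out`: `vectors.txt`, `freqs.tsv`,
#' `inventory.tsv`, and with gold `report.tsv` + `ap.tsv`; `run.yaml`
#' records the config, its hash and per-stage counts. A rerun with the same
#' config and inputs reproduces a byte-identical inventory.
#'
#' @param cfg a `run_config` (see [load_run_config()]).
#' @return list with the fitted `dsm`, the `term_inventory`, the
#'   `eval_report` (or `NULL`) and the summary list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (key in c("corpus", "dict", "out")) {
    if (is.null(cfg[[key]])) stop("config is missing '", key, "'", call. = FALSE)
  }
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(cfg))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  corpus <- stage("read", read_corpus(cfg$corpus, mode = cfg$corpus_mode))
  dict <- stage("dictionary", load_dictionary(cfg$dict))
  dcfg <- dsm_config(window = cfg$window, dim = cfg$dim,
                     min_count = cfg$min_count, seed = cfg$seed)
  extra <- if (!is.null(cfg$epochs)) list(epochs = cfg$epochs) else list()
  fit <- stage("train", do.call(dsm, c(list(corpus, dict, method = cfg$method,
                                            compose = isTRUE(cfg$compose),
                                            config = dcfg), extra)))
  stage("vectors", write_vectors(fit$space, file.path(cfg$out, "vectors.txt")))
  writeLines(paste0(names(fit$freqs), "\t", fit$freqs),
             file.path(cfg$out, "freqs.tsv"), useBytes = TRUE)

  inv <- stage("inventory",
               build_inventory(fit$space, fit$freqs, min_freq = cfg$min_freq,
                               n = cfg$top_n))
  write_inventory(inv, file.path(cfg$out, "inventory.tsv"))

  report <- NULL
  if (!is.null(cfg$gold)) {
    gold <- stage("gold", load_reference_standard(cfg$gold))
    queries <- intersect(vapply(names(gold), term_surface, ""),
                         rownames(fit$space$vectors))
    rankings <- lapply(queries, top_n, space = fit$space,
                       n = nrow(fit$space$vectors))
    report <- stage("evaluate",
                    evaluate_model(rankings, gold,
                                   vocab = rownames(fit$space$vectors),
                                   model_id = paste0(cfg$method,
                                                     if (isTRUE(cfg$compose)) "-BAM")))
    write_eval_report(report, file.path(cfg$out, "report.tsv"),
                      file.path(cfg$out, "ap.tsv"))
  }

  summary <- list(config = unclass(cfg), config_hash = hash,
                  n_documents = length(corpus),
                  n_dictionary_entries = nrow(dict),
                  n_terms_tagged = length(fit$freqs),
                  n_occurrences = sum(fit$freqs),
                  vocabulary_size = nrow(fit$full_space$vectors),
                  n_terms_vectorized = nrow(fit$space$vectors),
                  n_compositions_excluded = fit$space$provenance$n_excluded,
                  n_inventory_entries = length(inv),
                  map = if (!is.null(report)) report$map)
  yaml::write_yaml(summary, file.path(cfg$out, "run.yaml"))
  if (cfg$log_level != "quiet") {
    message("pipeline complete [", hash, "]: ", length(inv),
            " inventory entries",
            if (!is.null(report)) sprintf(", MAP %.4f", report$map))
  }
  invisible(list(fit = fit, inventory = inv, report = report,
                 summary = summary))
}

#' Planted-synonym recovery experiment
#'
#' Fits one model variant on a synthetic benchmark and scores how well each
#' planted name retrieves its group partners: every member queries the pool
#' of all planted names, and the rankings are evaluated against the
#' symmetric planted gold standard.
#'
#' @param data a `synth_data`.
#' @param method `"count"`, `"cbow"` or `"glove"`.
#' @param compose use the additive compositional variant.
#' @param config a `dsm_config`; its seed controls training randomness.
#' @param n accuracy cutoff reported as `accuracy` (default 10).
#' @param ... passed to [dsm()] (e.g. `epochs`).
#' @return list with `accuracy` (top-`n` accuracy), `report` (full
#'   `eval_report`), `fit`.
#' @export
benchmark_recovery <- function(data, method = "count", compose = FALSE,
                               config = dsm_config(), n = 10L, ...) {
  fit <- dsm(data$corpus, data$dictionary, method = method, compose = compose,
             config = config, ...)
  gold <- planted_gold(data)
  queries <- intersect(vapply(names(gold), term_surface, ""),
                       rownames(fit$space$vectors))
  pool <- intersect(vapply(names(planted_gold(data)), term_surface, ""),
                    rownames(fit$space$vectors))
  rankings <- lapply(queries, top_n, space = fit$space, pool = pool,
                     n = length(pool))
  report <- evaluate_model(rankings, gold, vocab = pool,
                           model_id = paste0(method, if (compose) "-BAM"))
  acc <- report$per_n$accuracy[report$per_n$n == n]
  list(accuracy = acc, report = report, fit = fit)
}
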