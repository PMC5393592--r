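# Synthetic corpus generator with planted synonym structure.
#
# The generator emulates the statistical regime distributional models rely
# on: a Zipfian background vocabulary, and planted synonym groups whose
# members occur in text surrounded by a group-specific "signature" context
# distribution. Multi-word names are emitted as plain space-separated words
# (the tagger joins them); their component words additionally occur
# standalone in the background, emulating genus/epithet words that appear
# across many species mentions and dilute single-word component vectors.

# run code under a given seed without disturbing the caller's RNG state
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic benchmark configuration
#'
#' Defaults are the package's standard benchmark: a 2000-word Zipf(1.1)
#' background vocabulary, 500 documents of 200 background tokens, 20 planted
#' synonym groups of 2 members, 15 signature context words per group and a
#' signature rate of 0.9.
#'
#' @param vocab_size background vocabulary size.
#' @param zipf_exponent exponent of the Zipfian rank-frequency law.
#' @param n_docs,doc_length corpus shape (background tokens per document).
#' @param n_groups,group_size planted synonym groups and members per group.
#' @param signature_size signature context words per group (disjoint across
#'   groups by default, drawn from the background vocabulary below the top
#'   ranks).
#' @param signature_pool_size optional size of a shared word pool from which
#'   every group samples its signature; smaller pools make group signatures
#'   overlap, giving a harder benchmark. `NULL` (default) keeps signatures
#'   disjoint.
#' @param signature_rate probability that a window neighbour of a planted
#'   name is drawn from the group signature rather than left as background.
#' @param multiword_fraction fraction of groups whose names are two-word
#'   (genus + epithet) names.
#' @param shared_component_prob probability that a group's variants share
#'   one component word (genus or epithet).
#' @param plants_per_doc planted name occurrences per document.
#' @param component_background_rate standalone background occurrences of
#'   name component words, as a multiple of `plants_per_doc` per document.
#' @param seed integer seed; identical configs generate identical data.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(vocab_size = 2000L, zipf_exponent = 1.1,
                         n_docs = 500L, doc_length = 200L,
                         n_groups = 20L, group_size = 2L,
                         signature_size = 15L, signature_rate = 0.9,
                         signature_pool_size = NULL,
                         multiword_fraction = 0.5,
                         shared_component_prob = 0.5,
                         plants_per_doc = 8L,
                         component_background_rate = 2,
                         seed = 1L) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              zipf_exponent = zipf_exponent,
              n_docs = as.integer(n_docs), doc_length = as.integer(doc_length),
              n_groups = as.integer(n_groups), group_size = as.integer(group_size),
              signature_size = as.integer(signature_size),
              signature_rate = signature_rate,
              signature_pool_size = if (!is.null(signature_pool_size))
                as.integer(signature_pool_size),
              multiword_fraction = multiword_fraction,
              shared_component_prob = shared_component_prob,
              plants_per_doc = as.integer(plants_per_doc),
              component_background_rate = component_background_rate,
              seed = as.integer(seed))
  probs <- c(cfg$signature_rate, cfg$multiword_fraction, cfg$shared_component_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]",
                                       call. = FALSE)
  if (cfg$group_size < 2L) stop("group_size must be >= 2", call. = FALSE)
  n_reserved <- min(100L, cfg$vocab_size %/% 10L)
  sig_budget <- if (is.null(cfg$signature_pool_size))
    cfg$n_groups * cfg$signature_size else cfg$signature_pool_size
  if (!is.null(cfg$signature_pool_size) &&
      cfg$signature_pool_size < cfg$signature_size) {
    stop("signature_pool_size must be >= signature_size", call. = FALSE)
  }
  if (sig_budget > cfg$vocab_size - n_reserved) {
    stop("infeasible config: signatures exceed the vocabulary budget",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic corpus with planted synonym groups
#'
#' Background tokens are drawn from a Zipf distribution. Each document embeds
#' `plants_per_doc` occurrences of planted names (members drawn uniformly);
#' each window neighbour (3 tokens per side) of a planted occurrence is,
#' with probability `signature_rate`, replaced by a word from the group's
#' signature. Group signatures are disjoint word sets sampled outside the
#' top Zipf ranks, so planted similarity is identifiable. The first member
#' of each group is its preferred name.
#'
#' @param config a `synth_config`.
#' @return list of class `synth_data`: `corpus` (named list of token
#'   vectors), `dictionary` (a `term_dictionary`), `gold` (a
#'   `reference_standard` mapping each preferred name to the other group
#'   members), `manifest` (per-group truth: members, preferred, signature,
#'   sharing structure), `config`.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    V <- config$vocab_size
    bg_words <- sprintf("w%05d", seq_len(V))
    zipf_p <- (1 / seq_len(V)^config$zipf_exponent)
    zipf_p <- zipf_p / sum(zipf_p)

    # signatures sampled below the most frequent ranks; disjoint across
    # groups unless a shared pool forces overlap
    n_reserved <- min(100L, V %/% 10L)
    if (is.null(config$signature_pool_size)) {
      sig_pool <- sample(bg_words[(n_reserved + 1L):V],
                         config$n_groups * config$signature_size)
      signatures <- split(sig_pool,
                          rep(seq_len(config$n_groups),
                              each = config$signature_size))
    } else {
      sig_pool <- sample(bg_words[(n_reserved + 1L):V],
                         config$signature_pool_size)
      signatures <- lapply(seq_len(config$n_groups), function(g)
        sample(sig_pool, config$signature_size))
    }

    groups <- vector("list", config$n_groups)
    for (g in seq_len(config$n_groups)) {
      multi <- stats::runif(1) < config$multiword_fraction
      if (multi) {
        shared <- stats::runif(1) < config$shared_component_prob
        share_genus <- stats::runif(1) < 0.5
        members <- character(config$group_size)
        shared_word <- NA_character_
        if (shared && share_genus) {
          shared_word <- sprintf("Genus%03d", g)
          for (m in seq_len(config$group_size)) {
            members[m] <- paste(shared_word, sprintf("epi%03d%s", g, letters[m]))
          }
        } else if (shared) {
          shared_word <- sprintf("epi%03dz", g)
          for (m in seq_len(config$group_size)) {
            members[m] <- paste(sprintf("Genus%03d%s", g, letters[m]), shared_word)
          }
        } else {
          for (m in seq_len(config$group_size)) {
            members[m] <- paste(sprintf("Genus%03d%s", g, letters[m]),
                                sprintf("epi%03d%s", g, letters[m]))
          }
        }
        kind <- "scientific"
      } else {
        members <- sprintf("vern%03d%s", g, letters[seq_len(config$group_size)])
        kind <- "vernacular"
        shared <- FALSE
        shared_word <- NA_character_
      }
      groups[[g]] <- list(members = members, preferred = members[[1L]],
                          kind = kind, multiword = multi,
                          shared_component = multi && shared,
                          shared_word = shared_word,
                          signature = signatures[[g]])
    }

    members_flat <- unlist(lapply(groups, `[[`, "members"))
    member_group <- rep(seq_len(config$n_groups),
                        vapply(groups, function(g) length(g$members), 0L))
    member_tokens <- strsplit(members_flat, " ", fixed = TRUE)
    comp_pool <- unique(unlist(member_tokens[lengths(member_tokens) > 1L]))

    w <- 3L # signature window, matching the models' default context window
    corpus <- vector("list", config$n_docs)
    for (d in seq_len(config$n_docs)) {
      toks <- bg_words[sample.int(V, config$doc_length, replace = TRUE,
                                  prob = zipf_p)]
      # standalone component occurrences: component words also appear inside
      # other species mentions, i.e. surrounded by a random group's
      # signature contexts — this dilutes and corrupts single-word
      # component vectors the way shared genus/epithet words are diluted in
      # real corpora
      if (length(comp_pool) > 0L && config$component_background_rate > 0) {
        n_ins <- round(config$component_background_rate * config$plants_per_doc)
        avail <- (w + 1L):(length(toks) - w)
        pos <- sample(avail, min(n_ins, length(avail)))
        toks[pos] <- sample(comp_pool, length(pos), replace = TRUE)
        for (p in pos) {
          sig <- groups[[sample.int(config$n_groups, 1L)]]$signature
          nb <- c((p - w):(p - 1L), (p + 1L):(p + w))
          use_sig <- stats::runif(length(nb)) < config$signature_rate
          toks[nb[use_sig]] <- sample(sig, sum(use_sig), replace = TRUE)
        }
      }
      # plant one name occurrence per equal-length block
      block <- config$doc_length %/% config$plants_per_doc
      out <- list()
      prev <- 0L
      for (p in seq_len(config$plants_per_doc)) {
        lo <- (p - 1L) * block + 1L
        hi <- min(p * block, config$doc_length)
        if (hi - lo < 2L * w + 2L) next
        at <- sample((lo + w):(hi - w), 1L)
        mi <- sample.int(length(members_flat), 1L)
        sig <- groups[[member_group[[mi]]]]$signature
        nb <- c((at - w):(at - 1L), (at + 1L):(at + w))
        use_sig <- stats::runif(length(nb)) < config$signature_rate
        toks[nb[use_sig]] <- sample(sig, sum(use_sig), replace = TRUE)
        out[[length(out) + 1L]] <- c(toks[prev + seq_len(at - 1L - prev)],
                                     member_tokens[[mi]])
        # re-index: emitted up to position at (name replaces the token there)
        prev <- at
      }
      out[[length(out) + 1L]] <- toks[prev + seq_len(config$doc_length - prev)]
      corpus[[d]] <- unlist(out, use.names = FALSE)
    }
    names(corpus) <- sprintf("doc%04d", seq_len(config$n_docs))

    dict <- term_dictionary(members_flat,
                            unlist(lapply(groups, function(g)
                              rep(g$kind, length(g$members)))))
    gold <- structure(lapply(groups, function(g) g$members[-1L]),
                      class = "reference_standard")
    names(gold) <- vapply(groups, `[[`, "", "preferred")
    structure(list(corpus = corpus, dictionary = dict, gold = gold,
                   manifest = list(groups = groups,
                                   n_groups = config$n_groups,
                                   n_members = length(members_flat)),
                   config = config),
              class = "synth_data")
  })
}

#' @export
print.synth_data <- function(x, ...) {
  cat("<synth_data> ", length(x$corpus), " docs, ",
      x$manifest$n_groups, " planted groups (",
      x$manifest$n_members, " names)\n", sep = "")
  invisible(x)
}

#' Shared-component composition benchmark
#'
#' Generates a benchmark where every planted name is a two-word
#' (genus + epithet) name and variant pairs share exactly one component word
#' when `shared_component_prob = 1` (and none when it is 0) — the regime in
#' which additive composition is expected to help (or hurt).
#'
#' @param config a `synth_config`; `multiword_fraction` is forced to 1.
#' @param shared_component_prob sharing probability (default 1).
#' @return a `synth_data`.
#' @export
make_shared_component_benchmark <- function(config = synth_config(),
                                            shared_component_prob = 1) {
  config$multiword_fraction <- 1
  config$shared_component_prob <- shared_component_prob
  synth_generate(config)
}

#' Configuration of the compositional-regime benchmark
#'
#' The benchmark conditions under which additive composition is stressed:
#' confusable group signatures (drawn from a small shared pool), a low
#' signature rate, and heavy component dilution with wrong-group contexts.
#' Used with [make_shared_component_benchmark()] at
#' `shared_component_prob` 1 (composition should help: variants share a
#' component word) or 0 (composition should hurt: component vectors carry
#' mostly other species' contexts).
#'
#' @param seed integer seed.
#' @return a `synth_config`.
#' @export
composition_benchmark_config <- function(seed = 1L) {
  synth_config(signature_rate = 0.2, plants_per_doc = 6L,
               component_background_rate = 20, n_groups = 30L,
               signature_pool_size = 25L, signature_size = 15L, seed = seed)
}

#' Symmetric planted-synonym gold standard
#'
#' Maps every planted member (not only preferred names) to the other members
#' of its group, for recovery experiments where each member queries for its
#' partners.
#'
#' @param manifest the `manifest` of a `synth_data` (or a `synth_data`).
#' @return a `reference_standard`.
#' @export
planted_gold <- function(manifest) {
  if (inherits(manifest, "synth_data")) manifest <- manifest$manifest
  recs <- list()
  for (g in manifest$groups) {
    for (m in g$members) recs[[m]] <- setdiff(g$members, m)
  }
  structure(recs, class = "reference_standard")
}

#' Write synthetic benchmark artifacts to a directory
#'
#' Emits `corpus.txt` (line per document), `dictionary.tsv`, `gold.tsv` and
#' `manifest.json`. Identical configs produce byte-identical files.
#'
#' @param x a `synth_data`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(x$corpus, file.path(dir, "corpus.txt"))
  writeLines(paste0(x$dictionary$name, "\t", x$dictionary$kind),
             file.path(dir, "dictionary.tsv"), useBytes = TRUE)
  write_reference_standard(x$gold, file.path(dir, "gold.tsv"))
  jsonlite::write_json(
    list(n_groups = x$manifest$n_groups, n_members = x$manifest$n_members,
         groups = lapply(x$manifest$groups, function(g)
           g[c("members", "preferred", "kind", "multiword",
               "shared_component", "shared_word", "signature")])),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    na = "null")
  invisible(dir)
}

#' Generate a synthetic reference standard with controlled structure
#'
#' Builds a binomial-style reference standard with a given number of
#' preferred names and total variants (every preferred name gets at least
#' one variant; the surplus is spread at random), and optionally a fixed
#' number of preferred names whose variants share a component word. Useful
#' for recomputing summary ratios of curated checklists from their published
#' counts.
#'
#' @param n_preferred number of preferred names.
#' @param n_variants total number of variants (`>= n_preferred`).
#' @param n_shared_preferred preferred names with at least one
#'   component-sharing variant (genus shared).
#' @param seed RNG seed.
#' @return a `reference_standard`.
#' @export
synth_reference_standard <- function(n_preferred, n_variants,
                                     n_shared_preferred = 0L, seed = 1L) {
  stopifnot(n_variants >= n_preferred, n_shared_preferred <= n_preferred)
  local_seed(seed, {
    pref <- sprintf("Prefgen%04d prefepi%04d", seq_len(n_preferred),
                    seq_len(n_preferred))
    extra <- sample.int(n_preferred, n_variants - n_preferred, replace = TRUE)
    n_per <- 1L + tabulate(extra, nbins = n_preferred)
    shared <- seq_len(n_preferred) <= n_shared_preferred
    recs <- vector("list", n_preferred)
    for (i in seq_len(n_preferred)) {
      genus <- if (shared[[i]]) sprintf("Prefgen%04d", i)
               else sprintf("Vargen%04d", i)
      recs[[i]] <- sprintf("%s varepi%04d%s", genus, i,
                           letters[seq_len(n_per[[i]])])
    }
    names(recs) <- pref
    structure(recs, class = "reference_standard")
  })
}
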