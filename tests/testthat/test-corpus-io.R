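test_that("tokenizer splits on whitespace and strips edge punctuation", {
  expect_equal(tokenize_text("Panthera leo roams."), c("Panthera", "leo", "roams"))
  expect_equal(tokenize_text("  great-gray   owl,  "), c("great-gray", "owl"))
  expect_equal(tokenize_text(""), character())
})

test_that("read_corpus is deterministic over directories and line files", {
  dir <- withr::local_tempdir()
  writeLines("Panthera leo roams.", file.path(dir, "b.txt"))
  writeLines(c("first doc here", "", "second doc here"), file.path(dir, "a.txt"))
  docs <- read_corpus(dir, mode = "dir")
  expect_equal(names(docs), c("a.txt", "b.txt"))
  expect_equal(docs[["b.txt"]], c("Panthera", "leo", "roams"))
  expect_identical(docs, read_corpus(dir, mode = "dir"))

  f <- file.path(dir, "lines.txt")
  writeLines(c("one two", "", "three", "   ", "four five six"), f)
  line_docs <- read_corpus(f, mode = "line")
  expect_length(line_docs, 3L)
  expect_equal(line_docs[[3L]], c("four", "five", "six"))

  expect_error(read_corpus(file.path(dir, "nope"), mode = "dir"), "exist")
})

test_that("empty directory yields an empty corpus", {
  dir <- withr::local_tempdir()
  expect_length(read_corpus(dir, mode = "dir"), 0L)
})

test_that("dictionary loading deduplicates and records kinds", {
  f <- withr::local_tempfile(lines = c("Panthera leo", "lion",
                                       "Panthera leo",
                                       "Tachycineta bicolor\tscientific"))
  d <- suppressMessages(load_dictionary(f))
  expect_equal(nrow(d), 3L)
  expect_equal(d$kind[d$name == "Tachycineta bicolor"], "scientific")
  expect_equal(d$kind[d$name == "lion"], "unknown")

  blank <- withr::local_tempfile(lines = c("", "   ", ""))
  expect_warning(d0 <- load_dictionary(blank), "no entries")
  expect_equal(nrow(d0), 0L)
})

test_that("reference standard parses variants and rejects empty rows", {
  f <- withr::local_tempfile(lines = c(
    "Actitis macularius\tActitis macularia|Tringa macularia|spotted sandpiper",
    "Cissampelos pareira\tvelvetleaf",
    "Abutilon theophrasti\tAbutilon abutilon|velvetleaf"))
  rs <- load_reference_standard(f)
  expect_length(rs, 3L)
  expect_equal(rs[["Actitis macularius"]],
               c("Actitis macularia", "Tringa macularia", "spotted sandpiper"))
  # polysemous vernacular retained under both preferred names
  expect_true("velvetleaf" %in% rs[["Cissampelos pareira"]])
  expect_true("velvetleaf" %in% rs[["Abutilon theophrasti"]])

  bad <- withr::local_tempfile(lines = c("Good name\tvariant", "Bad name\t"))
  expect_error(load_reference_standard(bad), "line 2")
})

test_that("reference standard summaries and round trip", {
  rs <- synth_reference_standard(50, 80, n_shared_preferred = 10, seed = 9)
  s <- reference_standard_summary(rs)
  expect_equal(s$n_preferred, 50L)
  expect_equal(s$n_variants, 80L)
  expect_equal(s$total_names, 130L)
  expect_equal(s$avg_variants, round(80 / 50, 2))
  sh <- shared_component_summary(rs)
  expect_equal(sh$n_preferred_shared, 10L)
  expect_equal(sh$pct_preferred_shared, 20)

  f <- withr::local_tempfile()
  write_reference_standard(rs, f)
  expect_equal(unclass(load_reference_standard(f))[names(rs)], unclass(rs))
})

test_that("normalization lowercases, filters and lemmatizes but spares protected terms", {
  cfg <- norm_config(stopwords = c("the", "were"), lemmatize = TRUE)
  expect_equal(normalize_tokens(c("the", "great", "gray", "owl"), cfg),
               c("great", "gray", "owl"))
  expect_equal(normalize_tokens(c("Owls", "were", "seen"), cfg),
               c("owl", "seen"))
  # all-off config is the identity
  off <- norm_config(lowercase_context = FALSE, stopwords = NULL,
                     lemmatize = FALSE)
  toks <- c("The", "Great", "Owls")
  expect_equal(normalize_tokens(toks, off), toks)
  # protected (tagged) terms survive untouched
  expect_equal(normalize_tokens(c("The", "Panthera_leo", "Cats"), cfg,
                                protect = "Panthera_leo"),
               c("Panthera_leo", "cat"))
})

test_that("vector file round-trip preserves terms and values", {
  m <- matrix(rnorm(15), 3, 5,
              dimnames = list(c("Panthera_leo", "lion", "jaguar"), NULL))
  sp <- vector_space(m, provenance = list(model = "test"))
  f <- withr::local_tempfile()
  write_vectors(sp, f)
  rt <- read_vectors(f)
  expect_equal(rownames(rt$vectors), rownames(m))
  expect_equal(unname(rt$vectors), unname(m), tolerance = 1e-6)

  # corrupt row length is a format error naming the term
  lines <- readLines(f)
  lines[3] <- paste(strsplit(lines[3], " ")[[1]][1:5], collapse = " ")
  writeLines(lines, f)
  expect_error(read_vectors(f), "lion")

  empty <- vector_space(matrix(numeric(), 0, 3))
  expect_error(write_vectors(empty, withr::local_tempfile()), "empty")
})
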