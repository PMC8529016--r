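write_fixture <- function(rows, path = withr::local_tempfile(fileext = ".tsv",
                                                             .local_envir = parent.frame())) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

base_rows <- tibble::tibble(
  form = c("gatto", "gatti", "rosa", "rose"),
  lemma = c("gatto", "gatto", "rosa", "rosa"),
  pos = "noun",
  gender = c("M", "M", "F", "F"),
  number = c("SG", "PL", "SG", "PL"),
  token_freq = c(10L, 5L, 7L, 3L)
)

test_that("a well-formed file reads into an equal lexicon", {
  path <- write_fixture(base_rows)
  lex <- read_lexicon(path, corpus_size = 1e6, dialect = "generic")
  expect_s3_class(lex, "lexicon")
  expect_equal(nrow(lex), 4L)
  expect_equal(corpus_size(lex), 1e6)
  expect_equal(sort(lex$form), sort(base_rows$form))
  expect_equal(sum(lex$token_freq), sum(base_rows$token_freq))
  expect_equal(nrow(lexicon_rejects(lex)), 0L)
})

test_that("duplicate key rows are summed with a warning", {
  rows <- dplyr::bind_rows(base_rows, base_rows[1, ])
  rows$token_freq[5] <- 3L
  path <- write_fixture(rows)
  expect_warning(lex <- read_lexicon(path, corpus_size = 1e6, dialect = "generic"),
                 "summed")
  expect_equal(nrow(lex), 4L)
  expect_equal(lex$token_freq[lex$form == "gatto"], 13)
})

test_that("rows with unknown codes or malformed frequencies are rejected and reported", {
  rows <- base_rows
  rows$gender[2] <- "N"
  rows$token_freq <- as.character(rows$token_freq)
  rows$token_freq[3] <- "-4"
  path <- write_fixture(rows)
  expect_message(lex <- read_lexicon(path, corpus_size = 1e6, dialect = "generic"),
                 "rejected 2")
  expect_equal(nrow(lex), 2L)
  rej <- lexicon_rejects(lex)
  expect_setequal(rej$line, c(3L, 4L))  # header is line 1
  expect_true(any(grepl("gender", rej$reason)))
  expect_true(any(grepl("frequency", rej$reason)))
})

test_that("a missing required column is a fatal parse error naming the column", {
  path <- write_fixture(base_rows[, setdiff(names(base_rows), "lemma")])
  expect_error(read_lexicon(path, corpus_size = 1e6, dialect = "generic"),
               "lemma")
})

test_that("a majority of rejected rows aborts as a dialect mismatch", {
  rows <- base_rows
  rows$gender <- "X"
  path <- write_fixture(rows)
  expect_error(read_lexicon(path, corpus_size = 1e6, dialect = "generic"),
               "dialect")
})

test_that("composed and decomposed accented forms normalize to one entry", {
  composed <- "citt\u00e0"       # single precomposed a-grave
  decomposed <- "citta\u0300"    # a + combining grave accent
  expect_equal(normalize_form(decomposed), composed)
  lex <- make_lexicon(
    entry(c("Citt\u00c0", decomposed), composed, "noun", "F",
          c("SG", "PL"), c(5, 5))
  )
  expect_equal(unique(lex$form), composed)
  expect_equal(unique(extract_ending(lex$form)), "\u00e0")
})

test_that("merging annotations with frequencies carries undivided homograph counts", {
  freq <- tibble::tibble(form = c("cameriere", "camerieri", "cameriera"),
                         pos = "noun", token_freq = c(5232, 400, 300))
  annot <- tibble::tibble(
    form = c("cameriere", "cameriere", "camerieri", "cameriera"),
    pos = "noun",
    lemma = c("cameriere", "cameriera", "cameriere", "cameriera"),
    gender = c("M", "F", "M", "F"),
    number = c("SG", "PL", "PL", "SG")
  )
  lex <- merge_frequency_annotation(freq, annot, corpus_size = 1.9e9)
  hom <- lex[lex$form == "cameriere", ]
  expect_equal(nrow(hom), 2L)
  expect_equal(hom$token_freq, c(5232, 5232))
  expect_setequal(hom$lemma, c("cameriere", "cameriera"))
})

test_that("unmatched rows are reported and empty joins are fatal", {
  freq <- tibble::tibble(form = c("a", "b"), pos = "noun", token_freq = c(1, 2))
  annot <- tibble::tibble(form = c("a", "c"), pos = "noun", lemma = c("a", "c"),
                          gender = "M", number = "SG")
  expect_message(lex <- merge_frequency_annotation(freq, annot, 1e6),
                 "unmatched")
  expect_equal(nrow(lex), 1L)
  expect_equal(attr(lex, "unmatched_freq")$form, "b")
  expect_equal(attr(lex, "unmatched_annotation")$form, "c")

  annot2 <- annot
  annot2$form <- c("x", "y")
  expect_error(merge_frequency_annotation(freq, annot2, 1e6), "Empty join")
  freq_dup <- dplyr::bind_rows(freq, freq[1, ])
  expect_error(merge_frequency_annotation(freq_dup, annot, 1e6), "duplicate")
})

test_that("a bijective merge preserves every frequency", {
  freq <- tibble::tibble(form = c("alfa", "beta", "gamma"), pos = "noun",
                         token_freq = c(3, 5, 9))
  annot <- tibble::tibble(form = freq$form, pos = "noun", lemma = freq$form,
                          gender = "M", number = "SG")
  lex <- merge_frequency_annotation(freq, annot, 1e6)
  expect_equal(nrow(lex), 3L)
  expect_equal(sum(lex$token_freq), sum(freq$token_freq))
})

test_that("frequency standardization is per million corpus tokens", {
  expect_equal(standardize_frequency(1900, 1.9e9), 1.0)
  expect_equal(standardize_frequency(0, 1.9e9), 0.0)
  expect_equal(standardize_frequency(5232, 1.9e9), 5232 * 1e6 / 1.9e9)
  expect_equal(standardize_frequency(5232, 1.9e9), 2.7537, tolerance = 1e-4)
  expect_error(standardize_frequency(10, 0), "positive")
})

test_that("the written database table round-trips and is deterministic", {
  cfg <- mixed_config(seed = 101)
  lex <- generate_lexicon(cfg)$lexicon
  paradigms <- build_paradigms(lex)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_flexit_table(lex, paradigms, p1)
  write_flexit_table(lex, paradigms, p2)
  expect_identical(readLines(p1), readLines(p2))

  back <- read_lexicon(p1, corpus_size = corpus_size(lex), dialect = "flexit")
  proj <- c("form", "lemma", "pos", "gender", "number", "token_freq")
  expect_equal(as.data.frame(back[, proj]), as.data.frame(lex[, proj]),
               ignore_attr = TRUE)
  expect_equal(sum(back$token_freq), sum(lex$token_freq))
})

test_that("the written table carries endings and class labels", {
  lex <- make_lexicon(entry(c("gatto", "gatti"), "gatto", "noun", "M",
                            c("SG", "PL"), c(10, 4)))
  paradigms <- build_paradigms(lex)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_flexit_table(lex, paradigms, path)
  out <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(out$ending, c("i", "o"))  # PL rows sort before SG
  expect_equal(unique(out$class), "o_i")

  empty <- lexicon(base_rows[0, ], corpus_size = 1e6)
  write_flexit_table(empty, build_paradigms(empty), path)
  expect_equal(length(readLines(path)), 1L)  # header only
})
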