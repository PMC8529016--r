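test_that("shannon entropy matches closed forms and rejects degenerate input", {
  expect_equal(shannon_entropy(c(1, 1, 1, 1)), 2)
  expect_equal(shannon_entropy(c(8318, 0)), 0)
  expect_equal(shannon_entropy(c(23, 23)), 1)
  expect_error(shannon_entropy(c(0, 0)), "all-zero")
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")
  expect_error(shannon_entropy(numeric(0)))
})

test_that("entropy invariances hold against a direct-summation oracle", {
  withr::local_seed(991)
  for (i in seq_len(1000L)) {
    k <- sample(1:4, 1L)
    counts <- sample(0:20, k, replace = TRUE)
    if (sum(counts) == 0) counts[1L] <- 1L
    h <- shannon_entropy(counts)
    expect_equal(h, entropy_oracle(counts), tolerance = 1e-12)
    # bounds: 0 <= H <= log2(support size), 0 iff single support
    support <- sum(counts > 0)
    expect_gte(h, 0)
    expect_lte(h, log2(max(support, 1)) + 1e-12)
    if (support == 1L) expect_equal(h, 0)
    # permutation, scale, zero-padding invariance
    expect_equal(shannon_entropy(rev(counts)), h)
    expect_equal(shannon_entropy(counts * 7L), h)
    expect_equal(shannon_entropy(c(counts, 0, 0)), h)
  }
})

test_that("ending distributions count types and tokens per feature combination", {
  entries <- dplyr::bind_rows(
    entry("rosa", "rosa", "noun", "F", "SG", 10),
    entry("rose", "rosa", "noun", "F", "PL", 4),
    entry("poeta", "poeta", "noun", "M", "SG", 2)
  )
  types <- ending_distribution(entries, "noun", "type")
  a_row <- types[types$ending == "a", ]
  expect_equal(unlist(a_row[, c("F.PL", "F.SG", "M.PL", "M.SG")],
                      use.names = FALSE), c(0, 1, 0, 1))
  tokens <- ending_distribution(entries, "noun", "token")
  a_tok <- tokens[tokens$ending == "a", ]
  expect_equal(unlist(a_tok[, c("F.PL", "F.SG", "M.PL", "M.SG")],
                      use.names = FALSE), c(0, 10, 0, 2))
  expect_equal(nrow(types), 4L)  # always four rows, a/e/i/o
})

test_that("non-core endings go to the remainder line, not the four rows", {
  entries <- entry(c("blu", "quiz"), c("blu", "quiz"), "noun", "M", "SG", c(5, 3))
  d <- ending_distribution(entries, "noun", "type")
  expect_equal(sum(d$total), 0)
  expect_true(all(is.na(d$H)))
  expect_equal(attr(d, "other")$n, 2)
  d_tok <- ending_distribution(entries, "noun", "token")
  expect_equal(attr(d_tok, "other")$n, 8)
})

test_that("ending totals plus remainder conserve the distinct form-combination pairs", {
  lex <- generate_lexicon(mixed_config(seed = 21, ambiguity_rate = 0.05))$lexicon
  for (pos in c("noun", "adjective")) {
    sub <- tibble::as_tibble(lex)[lex$pos == pos, ]
    d <- ending_distribution(sub, pos, "type")
    n_pairs <- nrow(dplyr::distinct(sub, form, gender, number))
    expect_equal(sum(d$total) + attr(d, "other")$n, n_pairs)
  }
})

test_that("class distributions respect gender keys, token policy and capacity", {
  # single-gender classes pin entropy to zero
  g <- generate_lexicon(generator_config(
    dplyr::bind_rows(class_spec("noun", "o_i", 200, p_masculine = 1),
                     class_spec("noun", "a_e", 100, p_masculine = 0)),
    seed = 5
  ))
  p <- build_paradigms(g$lexicon)
  d <- class_distribution(p, g$lexicon, "noun", "type")
  o_i <- d[d$class == "o_i", ]
  expect_equal(c(o_i$F, o_i$M), c(0, 200))
  expect_equal(o_i$H, 0)
  expect_equal(d$H[d$class == "a_e"], 0)

  # the gender-changing o_a plural is credited to its attested gender
  lex <- make_lexicon(
    entry(c("uovo", "uova"), "uovo", "noun", c("M", "F"), c("SG", "PL"), c(30, 20))
  )
  pu <- build_paradigms(lex)
  tok <- class_distribution(pu, lex, "noun", "token")
  expect_equal(c(tok$F, tok$M), c(20, 30))

  # adjective capacity is 2 bits; noun capacity 1 bit
  mix <- generate_lexicon(mixed_config(seed = 31))$lexicon
  pm <- build_paradigms(mix)
  dn <- class_distribution(pm, mix, "noun", "type")
  da <- class_distribution(pm, mix, "adjective", "type")
  expect_true(all(dn$H <= 1 + 1e-12))
  expect_true(all(da$H <= 2 + 1e-12))
  # one-cell noun paradigms never reach the class table
  expect_false(any(grepl("NA", dn$class)))
})

test_that("token class tables exclude ambiguous forms", {
  lex <- make_lexicon(
    entry(c("re", "re"), "re", "noun", "M", c("SG", "PL"), c(9, 9)),
    entry(c("libro", "libri"), "libro", "noun", "M", c("SG", "PL"), c(5, 3))
  )
  p <- build_paradigms(lex)
  tok <- class_distribution(p, lex, "noun", "token")
  expect_false("Inv" %in% tok$class)     # re's tokens are ambiguous SG/PL
  expect_equal(tok$M[tok$class == "o_i"], 8)
  typ <- class_distribution(p, lex, "noun", "type")
  expect_equal(typ$M[typ$class == "Inv"], 1)  # but its type remains
})

test_that("rendered tables carry four-decimal proportions and entropies", {
  rows <- tibble::tibble(
    pos = "noun", unit = "type", ending = c("a", "o"),
    `F.PL` = c(23, 0), `F.SG` = c(4331, 5), `M.PL` = c(12, 7),
    `M.SG` = c(477, 6205)
  )
  rows$total <- rowSums(rows[, c("F.PL", "F.SG", "M.PL", "M.SG")])
  rows$H <- vapply(seq_len(2), function(i)
    shannon_entropy(unlist(rows[i, c("F.PL", "F.SG", "M.PL", "M.SG")])),
    numeric(1))
  path <- withr::local_tempfile(fileext = ".tsv")
  render_entropy_table(rows, path)
  txt <- readLines(path)
  expect_length(txt, 3L)
  a_fields <- strsplit(txt[2], "\t")[[1]]
  expect_equal(a_fields[6:9], c("(0.0047)", "(0.8943)", "(0.0025)", "(0.0985)"))
  o_fields <- strsplit(txt[3], "\t")[[1]]
  expect_equal(o_fields[11], "0.0221")

  render_entropy_table(rows[0, ], path)
  expect_length(readLines(path), 1L)
})

test_that("the full pipeline produces every table with consistent labels", {
  g <- generate_lexicon(mixed_config(seed = 77, ambiguity_rate = 0.05))
  out <- entropy_pipeline(g$lexicon)
  expect_named(out$tables,
               c("noun_ending_type", "noun_ending_token", "noun_class_type",
                 "noun_class_token", "adjective_ending_type",
                 "adjective_ending_token", "adjective_class_type",
                 "adjective_class_token"))
  expect_equal(out$tables$noun_ending_type$ending, c("a", "e", "i", "o"))
  expect_equal(nrow(out$ambiguity_summary), 2L)
  # type totals are ordered descending in class tables
  tt <- out$tables$noun_class_type$total
  expect_true(all(diff(tt) <= 0))
})
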