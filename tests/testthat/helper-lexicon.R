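# Shared builders for in-code fixtures.

# quick entry-table builder: each row "form lemma pos gender number freq"
entry <- function(form, lemma, pos, gender, number, freq, grade = NA_character_) {
  tibble::tibble(form = form, lemma = lemma, pos = pos, gender = gender,
                 number = number, token_freq = freq, grade = grade)
}

make_lexicon <- function(..., corpus_size = 1e6) {
  lexicon(dplyr::bind_rows(...), corpus_size = corpus_size)
}

# a mixed-structure generator configuration used by several suites
mixed_config <- function(seed, ambiguity_rate = 0, cell_dropout = 0,
                         n_fourway = 0L) {
  generator_config(
    dplyr::bind_rows(
      class_spec("noun", "o_i", 40, 0.9, cell_dropout),
      class_spec("noun", "a_e", 300, 0, cell_dropout),
      class_spec("noun", "e_i", 300, 1, cell_dropout),
      class_spec("noun", "a_i", 10, 0.8, cell_dropout),
      class_spec("noun", "o_a", 8, 1, cell_dropout),
      class_spec("noun", "o_a_i", 6, 1, cell_dropout),
      class_spec("noun", "Inv", 10, 0.6, cell_dropout),
      class_spec("adjective", "a_e o_i", 30, cell_dropout = cell_dropout),
      class_spec("adjective", "e_i e_i", 15, cell_dropout = cell_dropout),
      class_spec("adjective", "a_NA NA", 5, cell_dropout = cell_dropout)
    ),
    ambiguity_rate = ambiguity_rate, n_fourway = n_fourway, seed = seed
  )
}

# independent direct-summation entropy oracle (kept deliberately naive)
entropy_oracle <- function(counts) {
  total <- 0
  for (c in counts) total <- total + c
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / total
      h <- h - p * (log(p) / log(2))
    }
  }
  h
}
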