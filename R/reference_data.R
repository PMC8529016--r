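# Bundled plain-text reference data.

#' Published distributional counts of Italian noun and adjective inflection
#'
#' Type and token counts of Italian noun and adjective forms over gender
#' and number values, conditioned on inflectional ending and on
#' declensional class, as tabulated from a large web-corpus-derived
#' inflectional lexicon (about 72k annotated word forms; corpus of 1.9
#' billion tokens). Feeding each row's counts to [shannon_entropy()]
#' reproduces the published per-row entropy values.
#'
#' @return tibble in long format: `pos`, `conditioner` (`"ending"` or
#'   `"class"`), `unit` (`"type"`/`"token"`), `label`, `category`
#'   (feature combination, or gender for noun classes) and `count`.
#' @export
reference_counts <- function() {
  path <- system.file("extdata", "reference_counts.tsv",
                      package = "declentropy", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cccccd", progress = FALSE)
}

#' Worked-example lexicon of classic Italian exemplars
#'
#' A small hand-built lexicon covering one exemplar per noun declensional
#' class (libro, rosa, fiore, problema, uovo, re, sport), the main
#' ambiguity patterns (abitante, cameriere, portavoce) and the two fully
#' attested adjective classes (bello, grande). Frequencies are plausible
#' round numbers; homograph forms carry the same undivided count, as a
#' POS-tagged corpus merge would produce.
#'
#' @param corpus_size corpus size to attach (defaults to 1.9e9 tokens).
#' @return a [lexicon()].
#' @export
worked_example_lexicon <- function(corpus_size = 1.9e9) {
  path <- system.file("extdata", "worked_example_lexicon.tsv",
                      package = "declentropy", mustWork = TRUE)
  read_lexicon(path, corpus_size = corpus_size, dialect = "flexit")
}
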