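# Seeded synthetic lexica with the statistical structure the analysis
# assumes: declensional-class structure for nouns (two-cell paradigms,
# lemma-level gender) and adjectives (four-cell paradigms), defective
# paradigms via cell dropout, planted within-POS homographs, and Zipfian
# token frequencies assigned over all surface forms jointly.
#
# Stems are CV-alternating strings over a fixed consonant/vowel alphabet,
# always ending in a consonant, so the appended ending character is
# guaranteed to be the final character of every generated form.

SYNTH_CONSONANTS <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r",
                      "s", "t", "v", "z")
SYNTH_VOWELS <- c("a", "e", "i", "o", "u")

#' Specify one declensional class for the generator
#'
#' @param pos `"noun"` or `"adjective"`.
#' @param class_label class label in the grammar of
#'   [assign_noun_class()] / [assign_adjective_class()]: nouns
#'   `"<sg>_<pl>"` (e.g. `"o_i"`), `"Inv"`, or the over-abundant
#'   `"o_a_i"`; adjectives two space-separated gender parts (e.g.
#'   `"a_e o_i"`, `"a_NA NA"`) or `"Inv"`.
#' @param n_lemmas number of lemmas to draw.
#' @param p_masculine probability that a noun lemma is masculine
#'   (ignored for adjectives, whose four cells span both genders).
#' @param cell_dropout probability that each paradigm cell is unattested;
#'   a lemma always keeps at least one cell.
#' @return one-row tibble.
#' @export
class_spec <- function(pos, class_label, n_lemmas, p_masculine = 0.5,
                       cell_dropout = 0) {
  pos <- match.arg(pos, c("noun", "adjective"))
  if (n_lemmas < 0) rlang::abort("`n_lemmas` must be non-negative.")
  if (p_masculine < 0 || p_masculine > 1 || cell_dropout < 0 || cell_dropout > 1) {
    rlang::abort("`p_masculine` and `cell_dropout` must be probabilities.")
  }
  parse_class_label(pos, class_label)  # fatal if unparseable
  tibble(pos = pos, class_label = class_label, n_lemmas = as.integer(n_lemmas),
         p_masculine = p_masculine, cell_dropout = cell_dropout)
}

parse_class_label <- function(pos, label) {
  if (pos == "noun") {
    if (label == "Inv") return(list(type = "Inv"))
    if (label == "o_a_i") return(list(type = "over", sg = "o", pl = c("a", "i")))
    m <- regmatches(label, regexec("^([a-z])_([a-z])$", label))[[1L]]
    if (length(m) == 3L) return(list(type = "regular", sg = m[2L], pl = m[3L]))
    rlang::abort(sprintf("Unparseable noun class label '%s'.", label))
  }
  if (label == "Inv") return(list(type = "Inv"))
  parts <- strsplit(label, " ", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    rlang::abort(sprintf("Unparseable adjective class label '%s'.", label))
  }
  parse_part <- function(p) {
    if (p == "NA") return(c(NA_character_, NA_character_))
    m <- regmatches(p, regexec("^([a-z]|NA)_([a-z]|NA)$", p))[[1L]]
    if (length(m) != 3L) {
      rlang::abort(sprintf("Unparseable adjective class label '%s'.", label))
    }
    out <- m[2:3]
    out[out == "NA"] <- NA_character_
    out
  }
  f <- parse_part(parts[1L]); m <- parse_part(parts[2L])
  if (all(is.na(c(f, m)))) {
    rlang::abort(sprintf("Adjective class label '%s' attests no cell.", label))
  }
  list(type = "regular", f_sg = f[1L], f_pl = f[2L], m_sg = m[1L], m_pl = m[2L])
}

#' Generator configuration
#'
#' @param classes tibble of [class_spec()] rows (bind them with
#'   `dplyr::bind_rows()`).
#' @param zipf_exponent exponent s of the rank-frequency law
#'   `freq(rank) = freq_scale * rank^(-s)`.
#' @param freq_scale token frequency of the rank-1 form.
#' @param ambiguity_rate fraction of surface forms planted as within-POS
#'   homographs (class-intersection pairs: a masculine e_i singular forced
#'   to coincide with a feminine a_e plural).
#' @param n_fourway number of nouns planted as four-way invariants (one
#'   surface form attested in all four gender x number combinations).
#' @param corpus_size nominal source-corpus size carried by the lexicon.
#' @param seed integer seed; the same configuration always yields a
#'   byte-identical lexicon.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(classes, zipf_exponent = 1, freq_scale = 1e6,
                             ambiguity_rate = 0, n_fourway = 0L,
                             corpus_size = 1.9e9, seed = 1L) {
  classes <- as_tibble(classes)
  if (nrow(classes) == 0L || sum(classes$n_lemmas) == 0L) {
    rlang::abort("At least one class with n_lemmas > 0 is required.")
  }
  if (zipf_exponent <= 0) rlang::abort("`zipf_exponent` must be positive.")
  if (freq_scale <= 0) rlang::abort("`freq_scale` must be positive.")
  if (ambiguity_rate < 0 || ambiguity_rate > 1) {
    rlang::abort("`ambiguity_rate` must be a probability.")
  }
  structure(
    list(classes = classes, zipf_exponent = zipf_exponent,
         freq_scale = freq_scale, ambiguity_rate = ambiguity_rate,
         n_fourway = as.integer(n_fourway), corpus_size = corpus_size,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# unique CV-alternating stems ending in a consonant, min length 3
draw_stems <- function(n, reserved = character()) {
  stems <- character(0L)
  while (length(stems) < n) {
    k <- sample(1:3, n - length(stems) + 16L, replace = TRUE,
                prob = c(0.2, 0.5, 0.3))
    cand <- vapply(k, function(kk) {
      paste0(
        sample(SYNTH_CONSONANTS, 1L),
        paste0(sample(SYNTH_VOWELS, kk, replace = TRUE),
               sample(SYNTH_CONSONANTS, kk, replace = TRUE), collapse = "")
      )
    }, character(1L))
    cand <- setdiff(unique(cand), c(stems, reserved))
    stems <- c(stems, cand)
  }
  stems[seq_len(n)]
}

#' Generate a seeded synthetic lexicon with ground truth
#'
#' Draws unique stems per class, inflects them per the class label,
#' applies cell dropout, plants homographs, and assigns Zipfian token
#' frequencies over all surface forms jointly. Homograph forms carry the
#' same undivided frequency in each of their entries, as a POS-tagged
#' corpus merge would produce.
#'
#' @param config a [generator_config()].
#' @return list with `lexicon` (a [lexicon()]) and `truth`, itself a list:
#'   `lemmas` (pos, lemma, gender_key, class), `entries` (pos, lemma,
#'   form, gender, number), `planted` (forms whose homography was forced,
#'   with the mechanism).
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::local_seed(config$seed)
  specs <- config$classes

  lemma_rows <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    if (sp$n_lemmas == 0L) next
    lemma_rows[[i]] <- tibble(
      pos = sp$pos, class_label = sp$class_label,
      stem = NA_character_,
      gender = dplyr::if_else(
        stats::runif(sp$n_lemmas) < sp$p_masculine, "M", "F"
      ),
      cell_dropout = sp$cell_dropout
    )
  }
  lemmas <- dplyr::bind_rows(lemma_rows)
  lemmas$stem <- draw_stems(nrow(lemmas))

  # plant class-intersection homographs: a masculine e_i lemma and a
  # feminine a_e lemma share a stem, so the e_i singular and the a_e
  # plural coincide in <stem>e
  planted <- tibble(pos = character(), form = character(), kind = character())
  if (config$ambiguity_rate > 0) {
    n_forms_est <- estimate_n_forms(lemmas)
    target <- round(config$ambiguity_rate * n_forms_est)
    donors <- which(lemmas$pos == "noun" & lemmas$class_label == "e_i" &
                      lemmas$gender == "M")
    hosts <- which(lemmas$pos == "noun" & lemmas$class_label == "a_e" &
                     lemmas$gender == "F")
    n_pairs <- min(target, length(donors), length(hosts))
    if (n_pairs < target) {
      rlang::warn(sprintf(
        "Requested ~%d planted homographs but only %d e_i(M) x a_e(F) pairs are available; rate reduced.",
        target, n_pairs
      ))
    }
    if (n_pairs > 0L) {
      donors <- sample(donors, n_pairs)
      hosts <- sample(hosts, n_pairs)
      lemmas$stem[hosts] <- lemmas$stem[donors]
      planted <- tibble(pos = "noun",
                        form = paste0(lemmas$stem[donors], "e"),
                        kind = "class_intersection")
    }
  }

  entries <- inflect_lemmas(lemmas)

  # four-way invariants: one surface form attested in all four combos
  if (config$n_fourway > 0L) {
    stems4 <- draw_stems(config$n_fourway, reserved = lemmas$stem)
    forms4 <- paste0(stems4, "e")
    four <- tidyr::expand_grid(form = forms4, gender = GENDER_LEVELS,
                               number = c("SG", "PL"))
    four$pos <- "noun"
    four$lemma <- four$form
    four$class <- "Inv"
    four$gender_key <- four$gender
    entries <- dplyr::bind_rows(entries, four)
    planted <- dplyr::bind_rows(
      planted, tibble(pos = "noun", form = forms4, kind = "four_way")
    )
  }

  # joint Zipfian rank-frequency over all (pos, form); homographs share
  # one undivided count
  forms <- dplyr::distinct(entries, .data$pos, .data$form)
  forms$rank <- sample.int(nrow(forms))
  forms$token_freq <- pmax(
    1, round(config$freq_scale * forms$rank^(-config$zipf_exponent))
  )
  entries <- dplyr::inner_join(entries, forms, by = c("pos", "form"))
  entries$grade <- dplyr::if_else(entries$pos == "adjective",
                                  "positive", NA_character_)

  truth_lemmas <- dplyr::distinct(
    entries, .data$pos, .data$lemma, .data$gender_key, .data$class
  )
  truth_entries <- entries[, c("pos", "lemma", "form", "gender", "number")]
  lex <- lexicon(
    entries[, c("form", "lemma", "pos", "gender", "number", "token_freq", "grade")],
    corpus_size = config$corpus_size, dialect = "generic"
  )
  list(lexicon = lex,
       truth = list(lemmas = truth_lemmas, entries = truth_entries,
                    planted = planted))
}

estimate_n_forms <- function(lemmas) {
  per_label <- c("Inv" = 1, "o_a_i" = 3)
  n <- 0
  for (i in seq_len(nrow(lemmas))) {
    lab <- lemmas$class_label[i]
    if (lemmas$pos[i] == "noun") {
      n <- n + (if (lab %in% names(per_label)) per_label[[lab]] else 2)
    } else {
      if (lab == "Inv") { n <- n + 1; next }
      p <- parse_class_label("adjective", lab)
      ends <- c(p$f_sg, p$f_pl, p$m_sg, p$m_pl)
      n <- n + length(unique(ends[!is.na(ends)]))
    }
  }
  n
}

# build the cell entries for each lemma row, applying dropout
inflect_lemmas <- function(lemmas) {
  if (nrow(lemmas) == 0L) return(tibble())
  rows <- vector("list", nrow(lemmas))
  for (i in seq_len(nrow(lemmas))) {
    stem <- lemmas$stem[i]
    g <- lemmas$gender[i]
    flip <- if (g == "M") "F" else "M"
    lab <- lemmas$class_label[i]
    p <- parse_class_label(lemmas$pos[i], lab)
    if (lemmas$pos[i] == "noun") {
      cells <- switch(
        p$type,
        regular = tibble(form = paste0(stem, c(p$sg, p$pl)),
                         gender = g, number = c("SG", "PL")),
        Inv = {
          end <- sample(c("e", "i", "u"), 1L)
          tibble(form = paste0(stem, end), gender = g, number = c("SG", "PL"))
        },
        over = tibble(form = paste0(stem, c("o", "a", "i")),
                      gender = c(g, flip, g), number = c("SG", "PL", "PL"))
      )
      # the gender-changing o_a pattern: plural under the opposite gender
      if (p$type == "regular" && lab == "o_a") cells$gender[2L] <- flip
      lemma_name <- cells$form[1L]
      cls <- if (p$type == "regular") assign_noun_class(p$sg, p$pl) else lab
    } else {
      if (p$type == "Inv") {
        form <- paste0(stem, "u")
        cells <- tidyr::expand_grid(gender = GENDER_LEVELS,
                                    number = c("SG", "PL"))
        cells$form <- form
      } else {
        cells <- tibble(
          gender = c("F", "F", "M", "M"),
          number = c("SG", "PL", "SG", "PL"),
          ending = c(p$f_sg, p$f_pl, p$m_sg, p$m_pl)
        )
        cells <- cells[!is.na(cells$ending), , drop = FALSE]
        cells$form <- paste0(stem, cells$ending)
      }
      lemma_name <- cells$form[1L]
      cls <- lab
    }
    drop <- stats::runif(nrow(cells)) < lemmas$cell_dropout[i]
    if (all(drop)) drop[sample.int(nrow(cells), 1L)] <- FALSE
    cells <- cells[!drop, , drop = FALSE]
    cells$pos <- lemmas$pos[i]
    cells$lemma <- lemma_name
    cells$class <- cls
    cells$gender_key <- if (lemmas$pos[i] == "noun") g else NA_character_
    rows[[i]] <- cells[, c("pos", "lemma", "form", "gender", "number",
                           "class", "gender_key")]
  }
  dplyr::bind_rows(rows)
}

#' Expected ambiguity records for a generated lexicon
#'
#' Derives, from the generator's own entry-level ground truth, the exact
#' set of (form, pos, pattern) records that [detect_ambiguous_forms()]
#' must report on the generated lexicon: every surface form whose truth
#' entries span two or more feature combinations, whether planted
#' (class-intersection pairs, four-way invariants) or structural
#' (invariant paradigms, gender-syncretic adjective classes).
#'
#' @param truth the `truth` element returned by [generate_lexicon()].
#' @param pos `"noun"` or `"adjective"`.
#' @return tibble with columns `form`, `pos`, `pattern`, `n_combos`,
#'   sorted by form.
#' @export
plant_ambiguity_report <- function(truth, pos = c("noun", "adjective")) {
  pos <- match.arg(pos)
  ent <- truth$entries[truth$entries$pos == pos, , drop = FALSE]
  if (nrow(ent) == 0L) {
    return(tibble(form = character(), pos = character(),
                  pattern = character(), n_combos = integer()))
  }
  ent$combo <- paste(ent$gender, ent$number, sep = ".")
  out <- ent |>
    dplyr::group_by(.data$form) |>
    dplyr::summarise(
      pattern = paste(intersect(COMBO_LEVELS, unique(.data$combo)),
                      collapse = "-"),
      n_combos = dplyr::n_distinct(.data$combo),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_combos >= 2L)
  out$pos <- pos
  dplyr::arrange(out[, c("form", "pos", "pattern", "n_combos")], .data$form)
}
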