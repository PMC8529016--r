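# Shannon entropy of form-value distributions, in bits.
#
# A distribution of types or tokens over the four gender x number
# combinations (for an ending, or an adjective class) or over the two
# genders (for a noun class) is summarized by
# H = -sum_v p_v log2 p_v, p_v = c_v / sum(c), with 0 log 0 := 0.
# H = 0 means the conditioner maps to a single value combination
# (maximal transparency); the capacity is 1 bit for a two-cell noun
# paradigm and 2 bits for a four-cell adjective paradigm.

#' Shannon entropy of a count vector, in bits
#'
#' @param counts non-negative numeric vector with at least one positive
#'   entry; zero counts contribute nothing.
#' @return entropy in bits, in `[0, log2(sum(counts > 0))]`.
#' @export
shannon_entropy <- function(counts) {
  if (length(counts) == 0L || !is.numeric(counts) || anyNA(counts)) {
    rlang::abort("`counts` must be a numeric vector without NA.")
  }
  if (any(counts < 0)) rlang::abort("`counts` must be non-negative.")
  total <- sum(counts)
  if (total <= 0) rlang::abort("Entropy is undefined for an all-zero count vector.")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

entropy_or_na <- function(counts) {
  if (sum(counts) <= 0) NA_real_ else shannon_entropy(counts)
}

#' Distribution of forms over feature combinations, per inflectional ending
#'
#' For each of the four core endings -a, -e, -i, -o, counts how the
#' entries realize the four gender x number combinations, either as types
#' (distinct form x combination pairs) or as tokens (summed corpus
#' frequencies), and reports the Shannon entropy of each row. Entries with
#' an ending outside a/e/i/o are excluded from the four rows and reported
#' in the `other` attribute as a remainder line.
#'
#' Pass entries already filtered by the counting policy matching `unit`
#' ([apply_counting_policy()]): all entries for `unit = "type"`,
#' non-ambiguous entries for `unit = "token"`.
#'
#' @param entries entry tibble (one POS).
#' @param pos `"noun"` or `"adjective"` (used to label the output).
#' @param unit `"type"` or `"token"`.
#' @return tibble with one row per ending (alphabetical): `pos`, `unit`,
#'   `ending`, counts `F.PL`, `F.SG`, `M.PL`, `M.SG`, `total`, `H`
#'   (`NA` for an empty row). Attribute `other`: remainder line for
#'   non-core endings.
#' @export
ending_distribution <- function(entries, pos = c("noun", "adjective"),
                                unit = c("type", "token")) {
  pos <- match.arg(pos)
  unit <- match.arg(unit)
  entries <- as_tibble(entries)
  entries <- entries[entries$pos == pos, , drop = FALSE]
  entries$ending <- if (nrow(entries) > 0L) extract_ending(entries$form) else character()
  entries$combo <- paste(entries$gender, entries$number, sep = ".")
  core <- entries[entries$ending %in% CORE_ENDINGS, , drop = FALSE]
  rest <- entries[!entries$ending %in% CORE_ENDINGS, , drop = FALSE]

  counted <- count_by(core, c("ending", "combo"), unit)
  grid <- tidyr::expand_grid(ending = CORE_ENDINGS, combo = COMBO_LEVELS)
  wide <- grid |>
    dplyr::left_join(counted, by = c("ending", "combo")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0)) |>
    tidyr::pivot_wider(names_from = "combo", values_from = "n")
  out <- tibble(pos = pos, unit = unit, ending = wide$ending)
  out <- dplyr::bind_cols(out, wide[, COMBO_LEVELS])
  out$total <- rowSums(out[, COMBO_LEVELS])
  out$H <- vapply(seq_len(nrow(out)),
                  function(i) entropy_or_na(unlist(out[i, COMBO_LEVELS])),
                  numeric(1L))
  attr(out, "other") <- tibble(
    pos = pos, unit = unit,
    n = if (unit == "type") {
      nrow(dplyr::distinct(rest, .data$form, .data$combo))
    } else {
      sum(rest$token_freq)
    }
  )
  out
}

count_by <- function(entries, keys, unit) {
  if (nrow(entries) == 0L) {
    out <- tibble()
    for (k in keys) out[[k]] <- character()
    out$n <- double()
    return(out)
  }
  if (unit == "type") {
    entries |>
      dplyr::distinct(dplyr::across(dplyr::all_of(c(keys, "form")))) |>
      dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n") |>
      dplyr::mutate(n = as.double(.data$n))
  } else {
    entries |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(n = sum(.data$token_freq), .groups = "drop")
  }
}

#' Distribution of forms over value categories, per declensional class
#'
#' Noun classes are two-cell paradigms: the distribution per class is over
#' the two genders, with a capacity of 1 bit. Type counts tally lemmas by
#' their lemma-level gender; token counts sum the corpus frequencies of
#' the class's non-ambiguous forms by the gender each form is attested
#' with (so the gender-changing plural of an o_a paradigm is credited to
#' its attested plural gender). One-cell noun paradigms (class labels
#' containing `NA`) are excluded. Adjective classes are four-cell
#' paradigms: the distribution is over the four gender x number
#' combinations, capacity 2 bits; type counts tally attested
#' (lemma, combination) cells, token counts sum frequencies per
#' combination.
#'
#' The token unit applies the counting policy internally: tokens of
#' ambiguous forms (detected on the full lexicon for the given POS) are
#' excluded.
#'
#' @param paradigms tibble from [build_paradigms()].
#' @param lexicon the [lexicon()] the paradigms were built from.
#' @param pos `"noun"` or `"adjective"`.
#' @param unit `"type"` or `"token"`.
#' @return tibble with one row per class, ordered by descending total then
#'   label: `pos`, `unit`, `class`, the category counts (`F`, `M` for
#'   nouns; the four combinations for adjectives), `total`, `H`.
#' @export
class_distribution <- function(paradigms, lexicon, pos = c("noun", "adjective"),
                               unit = c("type", "token")) {
  pos <- match.arg(pos)
  unit <- match.arg(unit)
  pars <- paradigms[paradigms$pos == pos, , drop = FALSE]
  if (pos == "noun") pars <- pars[!grepl("NA", pars$class), , drop = FALSE]
  categories <- if (pos == "noun") GENDER_LEVELS else COMBO_LEVELS
  if (nrow(pars) == 0L) {
    out <- tibble(pos = character(), unit = character(), class = character())
    for (k in categories) out[[k]] <- double()
    out$total <- double()
    out$H <- double()
    return(out)
  }

  if (unit == "type") {
    if (pos == "noun") {
      counted <- pars |>
        dplyr::count(class = .data$class, category = .data$gender_key, name = "n") |>
        dplyr::mutate(n = as.double(.data$n))
    } else {
      cells <- paradigm_cells(pars)
      counted <- cells |>
        dplyr::count(class = .data$class, category = .data$combo, name = "n") |>
        dplyr::mutate(n = as.double(.data$n))
    }
  } else {
    records <- detect_ambiguous_forms(lexicon, pos)
    token_entries <- apply_counting_policy(lexicon, records)$token_entries
    token_entries <- token_entries[token_entries$pos == pos, , drop = FALSE]
    cells <- paradigm_cells(pars)
    joined <- dplyr::inner_join(
      token_entries, cells[, c("pos", "lemma", "gender", "number", "form", "class")],
      by = c("pos", "lemma", "gender", "number", "form")
    )
    joined$category <- if (pos == "noun") joined$gender else
      paste(joined$gender, joined$number, sep = ".")
    counted <- joined |>
      dplyr::group_by(class = .data$class, category = .data$category) |>
      dplyr::summarise(n = sum(.data$token_freq), .groups = "drop")
  }

  grid <- tidyr::expand_grid(class = unique(pars$class), category = categories)
  wide <- grid |>
    dplyr::left_join(counted, by = c("class", "category")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0)) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n")
  out <- tibble(pos = pos, unit = unit, class = wide$class)
  out <- dplyr::bind_cols(out, wide[, categories])
  out$total <- rowSums(out[, categories])
  out$H <- vapply(seq_len(nrow(out)),
                  function(i) entropy_or_na(unlist(out[i, categories])),
                  numeric(1L))
  out <- out[out$total > 0 | unit == "type", , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$total), .data$class)
}

# round half away from zero at `digits` decimals, then fixed-width format
format_fixed <- function(x, digits = 4L) {
  scaled <- sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
  out <- sprintf(paste0("%.", digits, "f"), scaled)
  out[is.na(x)] <- ""
  out
}

#' Render an entropy table to a tab-separated file
#'
#' Writes one row per distribution: the conditioner label, the category
#' counts, the row-internal proportions in parentheses to four decimals,
#' the total and the entropy H to four decimals (half away from zero).
#' Row order is taken from the input, which the distribution builders
#' already order deterministically (endings alphabetically, classes by
#' descending total).
#'
#' @param rows a tibble from [ending_distribution()] or
#'   [class_distribution()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_entropy_table <- function(rows, path) {
  label_col <- intersect(c("ending", "class"), names(rows))[1L]
  categories <- intersect(c(COMBO_LEVELS, GENDER_LEVELS), names(rows))
  out <- tibble(label = rows[[label_col]])
  names(out) <- label_col
  for (k in categories) out[[k]] <- rows[[k]]
  for (k in categories) {
    p <- rows[[k]] / rows$total
    out[[paste0("p_", k)]] <- dplyr::if_else(
      rows$total > 0, paste0("(", format_fixed(p), ")"), ""
    )
  }
  out$total <- rows$total
  out$H <- format_fixed(rows$H)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Run the full transparency pipeline on a lexicon
#'
#' Reconstructs paradigms, detects ambiguous forms, applies the
#' type-vs-token counting policy, and computes every ending-level and
#' class-level distribution with its entropy, for both parts of speech
#' and both counting units.
#'
#' @param lexicon a [lexicon()].
#' @return list with elements `paradigms`, `ambiguous` (named list of
#'   record tibbles per POS), `pattern_tables`, `ambiguity_summary`, and
#'   `tables`: a named list of distribution tibbles
#'   (`<pos>_<ending|class>_<unit>`).
#' @export
entropy_pipeline <- function(lexicon) {
  paradigms <- build_paradigms(lexicon)
  tables <- list()
  ambiguous <- list()
  patterns <- list()
  summaries <- list()
  for (pos in c("noun", "adjective")) {
    records <- detect_ambiguous_forms(lexicon, pos)
    ambiguous[[pos]] <- records
    patterns[[pos]] <- tabulate_patterns(records)
    summaries[[pos]] <- ambiguity_summary(lexicon, pos)
    split_entries <- apply_counting_policy(lexicon, records)
    tables[[paste0(pos, "_ending_type")]] <-
      ending_distribution(split_entries$type_entries, pos, "type")
    tables[[paste0(pos, "_ending_token")]] <-
      ending_distribution(split_entries$token_entries, pos, "token")
    tables[[paste0(pos, "_class_type")]] <-
      class_distribution(paradigms, lexicon, pos, "type")
    tables[[paste0(pos, "_class_token")]] <-
      class_distribution(paradigms, lexicon, pos, "token")
  }
  list(
    paradigms = paradigms,
    ambiguous = ambiguous,
    pattern_tables = patterns,
    ambiguity_summary = dplyr::bind_rows(summaries),
    tables = tables
  )
}
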