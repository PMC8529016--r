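# Within-POS homograph detection and the type-vs-token counting policy.
#
# A surface form attested under two or more gender x number combinations
# inside one part of speech is ambiguous: its corpus token count cannot be
# split across the combinations, because POS-level tagging cannot tell a
# waiter (M.SG, e_i class) from waitresses (F.PL, a_e class) when both
# surface as the same string. Forms homographic only ACROSS parts of
# speech are never ambiguous here: their token counts are tagged per POS.

#' Detect within-POS ambiguous forms
#'
#' Groups the lexicon by (form, pos) and reports every form attested under
#' at least two distinct feature combinations, regardless of why the
#' homography arises (distinct lemmas, declensional-class intersection, or
#' invariance).
#'
#' @param lexicon a [lexicon()] (or plain entry tibble).
#' @param pos `"noun"` or `"adjective"`.
#' @return tibble with one row per ambiguous form: `form`, `pos`,
#'   `combos` (list of feature combinations in fixed report order),
#'   `n_combos`, `pattern` (canonical dash-joined combo string, e.g.
#'   `"F.SG-M.SG"`), `member_lemmas` (list).
#' @export
detect_ambiguous_forms <- function(lexicon, pos = c("noun", "adjective")) {
  pos <- match.arg(pos)
  entries <- as_tibble(lexicon)
  entries <- entries[entries$pos == pos, , drop = FALSE]
  if (nrow(entries) == 0L) return(empty_ambiguity_records(pos))
  entries$combo <- paste(entries$gender, entries$number, sep = ".")
  recs <- entries |>
    dplyr::group_by(.data$form) |>
    dplyr::summarise(
      combos = list(intersect(COMBO_LEVELS, unique(.data$combo))),
      n_combos = dplyr::n_distinct(.data$combo),
      member_lemmas = list(sort(unique(.data$lemma))),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_combos >= 2L)
  if (nrow(recs) == 0L) return(empty_ambiguity_records(pos))
  recs$pattern <- vapply(recs$combos, paste, character(1L), collapse = "-")
  recs$pos <- pos
  dplyr::arrange(
    recs[, c("form", "pos", "combos", "n_combos", "pattern", "member_lemmas")],
    .data$form
  )
}

empty_ambiguity_records <- function(pos) {
  tibble(form = character(), pos = character(), combos = list(),
         n_combos = integer(), pattern = character(), member_lemmas = list())
}

#' Tabulate ambiguity patterns
#'
#' Counts ambiguous forms per feature-combination pattern, ordered by
#' descending pattern size and then lexicographically, with a final
#' `Total` row equal to the number of ambiguous forms.
#'
#' @param records output of [detect_ambiguous_forms()] for one POS.
#' @return tibble with columns `pattern` and `n_forms`.
#' @export
tabulate_patterns <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(pattern = "Total", n_forms = 0L))
  }
  tab <- records |>
    dplyr::count(.data$pattern, .data$n_combos, name = "n_forms") |>
    dplyr::arrange(dplyr::desc(.data$n_combos), .data$pattern)
  dplyr::bind_rows(
    tab[, c("pattern", "n_forms")],
    tibble(pattern = "Total", n_forms = nrow(records))
  )
}

#' Apply the type-vs-token counting policy
#'
#' Ambiguous forms keep their type frequencies (one type per attested
#' feature combination: the annotation list disambiguates types even when
#' the corpus count cannot be split), but their token frequencies are
#' excluded entirely, so token-level tables are computed on non-ambiguous
#' forms only.
#'
#' @param lexicon a [lexicon()] (typically restricted to one POS).
#' @param records output of [detect_ambiguous_forms()] for the same POS.
#' @return list with `type_entries` (all entries, plus a logical
#'   `ambiguous` provenance flag) and `token_entries` (entries whose form
#'   is not ambiguous, same flag always `FALSE`).
#' @export
apply_counting_policy <- function(lexicon, records) {
  entries <- as_tibble(lexicon)
  amb_key <- paste(records$form, records$pos, sep = "\r")
  entries$ambiguous <- paste(entries$form, entries$pos, sep = "\r") %in% amb_key
  token_entries <- entries[!entries$ambiguous, , drop = FALSE]
  if (nrow(entries) > 0L && nrow(token_entries) == 0L) {
    rlang::warn("All forms are ambiguous: token-level tables will be empty.")
  }
  list(type_entries = entries, token_entries = token_entries)
}

#' Ambiguity summary for one POS
#'
#' @param lexicon a [lexicon()].
#' @param pos `"noun"` or `"adjective"`.
#' @return one-row tibble: `pos`, `n_forms` (distinct forms), `n_ambiguous`,
#'   `proportion` of distinct forms that are ambiguous.
#' @export
ambiguity_summary <- function(lexicon, pos = c("noun", "adjective")) {
  pos <- match.arg(pos)
  entries <- as_tibble(lexicon)
  entries <- entries[entries$pos == pos, , drop = FALSE]
  records <- detect_ambiguous_forms(lexicon, pos)
  n_forms <- dplyr::n_distinct(entries$form)
  tibble(
    pos = pos,
    n_forms = n_forms,
    n_ambiguous = nrow(records),
    proportion = if (n_forms > 0L) nrow(records) / n_forms else NA_real_
  )
}
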