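# Paradigm reconstruction: endings are final characters, noun paradigms are
# two cells (SG/PL) keyed by lemma-level gender, adjective paradigms are four
# cells (F.SG, F.PL, M.SG, M.PL) keyed by lemma alone.

NOUN_CANONICAL_CLASSES <- c("o_i", "a_e", "e_i", "a_i", "o_a")

#' Extract the inflectional ending of a word form
#'
#' In Italian noun and adjective declension the inflectional ending is the
#' last phoneme and, orthographically, the last character of the form; it
#' is obtained by stripping the final character. Endings outside the core
#' vowel set a/e/i/o (e.g. invariable loans ending in a consonant or in
#' -u) are returned verbatim; [ending_category()] maps them to the
#' sentinel `"OTHER"` used by the four-ending report tables.
#'
#' @param form character vector of non-empty, normalized forms.
#' @return character vector of single-character endings.
#' @export
extract_ending <- function(form) {
  if (any(is.na(form) | !nzchar(form))) {
    rlang::abort("Cannot extract an ending from an empty form.")
  }
  substr(form, nchar(form), nchar(form))
}

#' Categorize an ending for the four-ending report tables
#' @param ending character vector of endings as returned by [extract_ending()].
#' @return the ending itself for a/e/i/o, `"OTHER"` otherwise.
#' @export
ending_category <- function(ending) {
  dplyr::if_else(ending %in% CORE_ENDINGS, ending, "OTHER")
}

#' Render gender x number as a feature combination
#' @param gender "F"/"M"; @param number "SG"/"PL".
#' @return factor with the fixed report ordering F.PL, F.SG, M.PL, M.SG.
#' @export
feature_combo <- function(gender, number) {
  factor(paste(gender, number, sep = "."), levels = COMBO_LEVELS)
}

#' Assign a noun declensional-class label
#'
#' The label couples the singular and plural endings (`"o_i"`, `"a_e"`,
#' `"e_i"`, `"a_i"`, `"o_a"` are the canonical classes). An invariant
#' paradigm (identical SG and PL surface forms) is always `"Inv"`,
#' regardless of its ending: invariance wins over ending-pair
#' classification. An attested SG/PL ending pair outside the canonical set
#' that is not invariant (e.g. sport/sports, corpus/corpora) is `"Other"`.
#' One-cell paradigms are labelled with `NA` in place of the missing
#' ending (`"o_NA"`, `"NA_i"`) and are excluded from class-level entropy
#' tables.
#'
#' @param sg_ending,pl_ending single-character endings, `NA` when the cell
#'   is unattested; vectorized.
#' @param invariant logical: SG and PL forms are identical.
#' @return character vector of class labels.
#' @export
assign_noun_class <- function(sg_ending, pl_ending, invariant = FALSE) {
  n <- max(length(sg_ending), length(pl_ending), length(invariant))
  sg <- rep_len(as.character(sg_ending), n)
  pl <- rep_len(as.character(pl_ending), n)
  inv <- rep_len(invariant, n)
  pair <- paste0(sg, "_", pl)
  out <- dplyr::case_when(
    inv ~ "Inv",
    is.na(sg) & is.na(pl) ~ NA_character_,
    is.na(sg) ~ paste0("NA_", pl),
    is.na(pl) ~ paste0(sg, "_NA"),
    pair %in% NOUN_CANONICAL_CLASSES ~ pair,
    TRUE ~ "Other"
  )
  out
}

# Class label for a noun paradigm that may be over-abundant (a plural cell
# attested with two endings): SG -o with PL -a and -i is the recognized
# over-abundant class "o_a_i"; any other over-abundant pattern falls into
# "Other".
noun_class_label <- function(sg_ending, pl_endings, invariant = FALSE) {
  pl_endings <- sort(unique(pl_endings[!is.na(pl_endings)]))
  if (invariant) return("Inv")
  if (length(pl_endings) > 1L) {
    if (identical(pl_endings, c("a", "i")) &&
        length(sg_ending) == 1L && !is.na(sg_ending) && sg_ending == "o") {
      return("o_a_i")
    }
    return("Other")
  }
  if (length(sg_ending) > 1L) return("Other")
  assign_noun_class(
    if (length(sg_ending) == 0L) NA_character_ else sg_ending,
    if (length(pl_endings) == 0L) NA_character_ else pl_endings
  )
}

#' Assign an adjective declensional-class label
#'
#' The label concatenates a feminine part and a masculine part, each
#' coupling the singular and plural endings of that gender, e.g.
#' `"a_e o_i"` (bello-type) or `"e_i e_i"` (grande-type). An unattested
#' cell is rendered `"NA"` inside the part (`"a_NA NA"`: only F.SG
#' attested); a gender with both cells unattested collapses to the single
#' token `"NA"` (`"NA o_i"`). A gender whose singular and plural share one
#' invariant surface form is rendered `"Inv"` in that slot; a paradigm
#' whose attested forms are all identical across genders and numbers is
#' the invariant class `"Inv"`.
#'
#' @param f_sg,f_pl,m_sg,m_pl endings of the four cells (`NA` when
#'   unattested).
#' @param f_invariant,m_invariant logical: that gender's SG and PL forms
#'   are identical.
#' @param all_invariant logical: every attested form is the same surface
#'   form, across genders and numbers.
#' @return single class label string.
#' @export
assign_adjective_class <- function(f_sg = NA, f_pl = NA, m_sg = NA, m_pl = NA,
                                   f_invariant = FALSE, m_invariant = FALSE,
                                   all_invariant = FALSE) {
  if (all_invariant) return("Inv")
  part <- function(sg, pl, inv) {
    if (is.na(sg) && is.na(pl)) return("NA")
    if (inv) return("Inv")
    paste0(ifelse(is.na(sg), "NA", sg), "_", ifelse(is.na(pl), "NA", pl))
  }
  paste(part(f_sg, f_pl, f_invariant), part(m_sg, m_pl, m_invariant))
}

#' Reconstruct inflectional paradigms from a lexicon
#'
#' Couples the endings attested for the same lemma. Nouns are grouped by
#' (lemma, gender) because a noun lemma is lexically specified for gender;
#' two lemma-level exceptions are recognized: (i) a lemma with exactly one
#' singular and one plural entry of opposite genders is coupled into one
#' paradigm (the gender-changing o_a pattern, uovo/uova), keyed by the
#' gender of its singular; (ii) a lemma with one singular and two plural
#' entries of distinct endings is coupled into one over-abundant paradigm
#' (the o_a_i pattern). Adjectives are grouped by lemma into four-cell
#' paradigms. A cell expected but unattested is tagged `NA`; identical
#' singular and plural forms set the `Inv` flag.
#'
#' @param lexicon a [lexicon()].
#' @return tibble with one row per paradigm: `pos`, `lemma`, `gender_key`
#'   (nouns; for adjectives `NA`), `class`, `flags` (comma-separated
#'   subset of Inv, NA, Other, OverAbundant), and the cell forms/endings
#'   (`sg_form`, `sg_ending`, `pl_form`, `pl_ending`, `pl_form_2`,
#'   `pl_ending_2` for nouns; `f_sg_form` ... `m_pl_ending` for
#'   adjectives).
#' @export
build_paradigms <- function(lexicon) {
  entries <- as_tibble(lexicon)
  entries$ending <- if (nrow(entries) > 0L) extract_ending(entries$form) else character()
  nouns <- build_noun_paradigms(entries[entries$pos == "noun", , drop = FALSE])
  adjs <- build_adjective_paradigms(entries[entries$pos == "adjective", , drop = FALSE])
  out <- dplyr::bind_rows(nouns, adjs)
  if (nrow(out) == 0L) return(out)
  dplyr::arrange(out, .data$pos, .data$lemma, .data$gender_key)
}

build_noun_paradigms <- function(entries) {
  if (nrow(entries) == 0L) return(tibble())
  stats <- entries |>
    dplyr::group_by(.data$lemma) |>
    dplyr::summarise(
      n_sg = sum(.data$number == "SG"),
      n_pl = sum(.data$number == "PL"),
      n_gender = dplyr::n_distinct(.data$gender),
      n_pl_end = dplyr::n_distinct(.data$ending[.data$number == "PL"]),
      .groups = "drop"
    )
  couple <- stats$lemma[
    (stats$n_sg == 1L & stats$n_pl == 1L & stats$n_gender == 2L) |
      (stats$n_sg == 1L & stats$n_pl == 2L & stats$n_pl_end == 2L)
  ]
  entries$group_gender <- dplyr::if_else(entries$lemma %in% couple,
                                         "*", entries$gender)
  grouped <- entries |>
    dplyr::group_by(.data$lemma, .data$group_gender) |>
    dplyr::arrange(.data$form, .by_group = TRUE) |>
    dplyr::summarise(
      sg_form = .data$form[.data$number == "SG"][1L],
      sg_ending = .data$ending[.data$number == "SG"][1L],
      n_sg = sum(.data$number == "SG"),
      pl_form = .data$form[.data$number == "PL"][1L],
      pl_ending = .data$ending[.data$number == "PL"][1L],
      pl_form_2 = .data$form[.data$number == "PL"][2L],
      pl_ending_2 = .data$ending[.data$number == "PL"][2L],
      sg_gender = .data$gender[.data$number == "SG"][1L],
      pl_gender = .data$gender[.data$number == "PL"][1L],
      pl_gender_2 = .data$gender[.data$number == "PL"][2L],
      any_gender = .data$gender[1L],
      .groups = "drop"
    )
  grouped$gender_key <- dplyr::if_else(grouped$group_gender == "*",
                                       dplyr::coalesce(grouped$sg_gender,
                                                       grouped$any_gender),
                                       grouped$group_gender)
  invariant <- !is.na(grouped$sg_form) & !is.na(grouped$pl_form) &
    grouped$sg_form == grouped$pl_form
  over <- !is.na(grouped$pl_ending_2) | grouped$n_sg > 1L
  grouped$class <- mapply(function(i) {
    sg <- grouped$sg_ending[i]
    noun_class_label(
      sg_ending = sg[!is.na(sg)],
      pl_endings = c(grouped$pl_ending[i], grouped$pl_ending_2[i]),
      invariant = invariant[i]
    )
  }, seq_len(nrow(grouped)))
  grouped$flags <- paradigm_flags(
    inv = invariant,
    na = is.na(grouped$sg_form) | is.na(grouped$pl_form),
    other = grouped$class == "Other",
    over = over | grouped$class == "o_a_i"
  )
  tibble(
    pos = "noun",
    lemma = grouped$lemma,
    gender_key = grouped$gender_key,
    class = grouped$class,
    flags = grouped$flags,
    sg_form = grouped$sg_form, sg_ending = grouped$sg_ending,
    pl_form = grouped$pl_form, pl_ending = grouped$pl_ending,
    pl_form_2 = grouped$pl_form_2, pl_ending_2 = grouped$pl_ending_2,
    sg_gender = grouped$sg_gender, pl_gender = grouped$pl_gender,
    pl_gender_2 = grouped$pl_gender_2
  )
}

build_adjective_paradigms <- function(entries) {
  if (nrow(entries) == 0L) return(tibble())
  cell_of <- function(df, g, n, what) {
    v <- df[[what]][df$gender == g & df$number == n]
    if (length(v) == 0L) NA_character_ else sort(v)[1L]
  }
  grouped <- entries |>
    dplyr::group_by(.data$lemma) |>
    dplyr::group_modify(function(df, key) {
      tibble(
        f_sg_form = cell_of(df, "F", "SG", "form"),
        f_sg_ending = cell_of(df, "F", "SG", "ending"),
        f_pl_form = cell_of(df, "F", "PL", "form"),
        f_pl_ending = cell_of(df, "F", "PL", "ending"),
        m_sg_form = cell_of(df, "M", "SG", "form"),
        m_sg_ending = cell_of(df, "M", "SG", "ending"),
        m_pl_form = cell_of(df, "M", "PL", "form"),
        m_pl_ending = cell_of(df, "M", "PL", "ending"),
        over = nrow(df) > nrow(dplyr::distinct(df, .data$gender, .data$number))
      )
    }) |>
    dplyr::ungroup()
  f_inv <- !is.na(grouped$f_sg_form) & !is.na(grouped$f_pl_form) &
    grouped$f_sg_form == grouped$f_pl_form
  m_inv <- !is.na(grouped$m_sg_form) & !is.na(grouped$m_pl_form) &
    grouped$m_sg_form == grouped$m_pl_form
  forms <- grouped[, c("f_sg_form", "f_pl_form", "m_sg_form", "m_pl_form")]
  all_inv <- vapply(seq_len(nrow(grouped)), function(i) {
    v <- unlist(forms[i, ], use.names = FALSE)
    v <- v[!is.na(v)]
    spans_number <- !all(is.na(c(grouped$f_sg_form[i], grouped$m_sg_form[i]))) &&
      !all(is.na(c(grouped$f_pl_form[i], grouped$m_pl_form[i])))
    length(v) >= 2L && length(unique(v)) == 1L && spans_number
  }, logical(1L))
  grouped$class <- vapply(seq_len(nrow(grouped)), function(i) {
    assign_adjective_class(
      grouped$f_sg_ending[i], grouped$f_pl_ending[i],
      grouped$m_sg_ending[i], grouped$m_pl_ending[i],
      f_invariant = f_inv[i], m_invariant = m_inv[i], all_invariant = all_inv[i]
    )
  }, character(1L))
  has_na_cell <- is.na(grouped$f_sg_form) | is.na(grouped$f_pl_form) |
    is.na(grouped$m_sg_form) | is.na(grouped$m_pl_form)
  grouped$flags <- paradigm_flags(
    inv = f_inv | m_inv | all_inv,
    na = has_na_cell,
    other = FALSE,
    over = grouped$over
  )
  tibble(
    pos = "adjective",
    lemma = grouped$lemma,
    gender_key = NA_character_,
    class = grouped$class,
    flags = grouped$flags,
    f_sg_form = grouped$f_sg_form, f_sg_ending = grouped$f_sg_ending,
    f_pl_form = grouped$f_pl_form, f_pl_ending = grouped$f_pl_ending,
    m_sg_form = grouped$m_sg_form, m_sg_ending = grouped$m_sg_ending,
    m_pl_form = grouped$m_pl_form, m_pl_ending = grouped$m_pl_ending
  )
}

paradigm_flags <- function(inv, na, other, over) {
  n <- length(inv)
  na <- rep_len(na, n); other <- rep_len(other, n); over <- rep_len(over, n)
  vapply(seq_along(inv), function(i) {
    paste(c("Inv"[inv[i]], "NA"[na[i]], "Other"[other[i]],
            "OverAbundant"[over[i]]), collapse = ",")
  }, character(1L))
}

#' Expand a paradigm table to one row per attested cell
#'
#' The long view of [build_paradigms()]: one row per (paradigm, attested
#' cell), keyed so that lexicon entries can be joined back by
#' (pos, lemma, gender, number, form). For nouns the entry-level gender of
#' a cell is the gender the form is attested with (which differs from
#' `gender_key` for the plural of a gender-changing o_a paradigm).
#'
#' @param paradigms tibble from [build_paradigms()].
#' @return tibble with columns `pos`, `lemma`, `gender_key`, `gender`,
#'   `number`, `combo`, `form`, `ending`, `class`, `flags`.
#' @export
paradigm_cells <- function(paradigms) {
  if (nrow(paradigms) == 0L) {
    return(tibble(pos = character(), lemma = character(),
                  gender_key = character(), gender = character(),
                  number = character(), combo = character(),
                  form = character(), ending = character(),
                  class = character(), flags = character()))
  }
  nouns <- paradigms[paradigms$pos == "noun", , drop = FALSE]
  adjs <- paradigms[paradigms$pos == "adjective", , drop = FALSE]
  out <- list()
  if (nrow(nouns) > 0L) {
    # each cell carries the gender it was attested with, which differs
    # from gender_key for the plural of a coupled o_a / o_a_i paradigm
    long <- dplyr::bind_rows(
      tibble(i = seq_len(nrow(nouns)), number = "SG",
             form = nouns$sg_form, ending = nouns$sg_ending,
             gender = nouns$sg_gender),
      tibble(i = seq_len(nrow(nouns)), number = "PL",
             form = nouns$pl_form, ending = nouns$pl_ending,
             gender = nouns$pl_gender),
      tibble(i = seq_len(nrow(nouns)), number = "PL",
             form = nouns$pl_form_2, ending = nouns$pl_ending_2,
             gender = nouns$pl_gender_2)
    )
    long <- long[!is.na(long$form), , drop = FALSE]
    out$nouns <- tibble(
      pos = "noun", lemma = nouns$lemma[long$i],
      gender_key = nouns$gender_key[long$i], gender = long$gender,
      number = long$number,
      combo = paste(long$gender, long$number, sep = "."),
      form = long$form, ending = long$ending,
      class = nouns$class[long$i], flags = nouns$flags[long$i]
    )
  }
  if (nrow(adjs) > 0L) {
    slots <- list(
      c("F", "SG", "f_sg_form", "f_sg_ending"),
      c("F", "PL", "f_pl_form", "f_pl_ending"),
      c("M", "SG", "m_sg_form", "m_sg_ending"),
      c("M", "PL", "m_pl_form", "m_pl_ending")
    )
    out$adjs <- dplyr::bind_rows(lapply(slots, function(s) {
      keep <- !is.na(adjs[[s[3L]]])
      tibble(
        pos = "adjective", lemma = adjs$lemma[keep],
        gender_key = NA_character_, gender = s[1L], number = s[2L],
        combo = paste(s[1L], s[2L], sep = "."),
        form = adjs[[s[3L]]][keep], ending = adjs[[s[4L]]][keep],
        class = adjs$class[keep], flags = adjs$flags[keep]
      )
    }))
  }
  dplyr::bind_rows(out)
}
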