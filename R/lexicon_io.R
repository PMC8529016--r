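#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Canonical category orders used throughout the report tables.
COMBO_LEVELS <- c("F.PL", "F.SG", "M.PL", "M.SG")
GENDER_LEVELS <- c("F", "M")
CORE_ENDINGS <- c("a", "e", "i", "o")

LEXICON_KEY <- c("form", "pos", "gender", "number", "lemma")

#' Built-in input dialects
#'
#' A dialect maps the column names of a tab-separated input file onto the
#' semantic fields of a lexicon entry. The `flexit` dialect matches the
#' column layout written by [write_flexit_table()]; `generic` expects a
#' plain `token_freq` column. Custom dialects can be supplied to
#' [read_lexicon()] as a named character vector with the same semantic
#' names.
#'
#' @format A named list of named character vectors
#'   (semantic field -> column name).
#' @export
lexicon_dialects <- list(
  flexit = c(
    form = "form", lemma = "lemma", pos = "pos", gender = "gender",
    number = "number", freq = "raw_freq", grade = "grade"
  ),
  generic = c(
    form = "form", lemma = "lemma", pos = "pos", gender = "gender",
    number = "number", freq = "token_freq", grade = "grade"
  )
)

resolve_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1L && is.null(names(dialect))) {
    if (!dialect %in% names(lexicon_dialects)) {
      abort(sprintf(
        "Unknown dialect '%s'; available: %s",
        dialect, paste(names(lexicon_dialects), collapse = ", ")
      ))
    }
    return(lexicon_dialects[[dialect]])
  }
  required <- c("form", "lemma", "pos", "gender", "number", "freq")
  if (!all(required %in% names(dialect))) {
    abort(sprintf(
      "A dialect must map at least: %s", paste(required, collapse = ", ")
    ))
  }
  dialect
}

#' Normalize a surface form
#'
#' Unicode NFC composition followed by lowercase folding, so that ending
#' extraction (which looks only at the final character) is stable across
#' composed/decomposed accented vowels (a grave-accented vowel must be one
#' character, not vowel + combining accent).
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_form <- function(x) {
  stringi::stri_trans_nfc(stringi::stri_trans_tolower(x))
}

normalize_code <- function(x) toupper(trimws(x))

normalize_pos <- function(x) {
  x <- tolower(trimws(x))
  x[x == "adj"] <- "adjective"
  x
}

#' Construct a lexicon from an entry table
#'
#' The canonical container of the package: a tibble of annotated inflected
#' word forms with token frequencies, carrying the source-corpus size (for
#' per-million standardization) and the input dialect as attributes.
#'
#' @param entries tibble/data.frame with columns `form`, `lemma`, `pos`
#'   (`"noun"`/`"adjective"`), `gender` (`"F"`/`"M"`), `number`
#'   (`"SG"`/`"PL"`), `token_freq` (non-negative integer); optionally
#'   `grade` and `source_id`.
#' @param corpus_size positive number: total token count of the source
#'   corpus.
#' @param dialect format tag (informational).
#' @param rejects optional tibble of rejected input rows (line, reason),
#'   attached for reporting.
#' @return a `lexicon` object (tibble subclass).
#' @export
lexicon <- function(entries, corpus_size, dialect = "generic", rejects = NULL) {
  if (missing(corpus_size) || length(corpus_size) != 1L ||
      !is.numeric(corpus_size) || is.na(corpus_size) || corpus_size <= 0) {
    abort("`corpus_size` must be a single positive number.")
  }
  entries <- as_tibble(entries)
  required <- c("form", "lemma", "pos", "gender", "number", "token_freq")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Missing lexicon columns: %s", paste(missing_cols, collapse = ", ")))
  }
  if (!"grade" %in% names(entries)) entries$grade <- NA_character_
  if (!"source_id" %in% names(entries)) entries$source_id <- NA_character_
  entries$form <- normalize_form(entries$form)
  entries$lemma <- normalize_form(entries$lemma)
  entries$pos <- normalize_pos(entries$pos)
  entries$gender <- normalize_code(entries$gender)
  entries$number <- normalize_code(entries$number)
  entries$token_freq <- as.double(entries$token_freq)
  validate_entries(entries)
  entries <- dplyr::arrange(entries, .data$pos, .data$lemma, .data$gender,
                            .data$number, .data$form)
  structure(
    entries[, c(required, "grade", "source_id")],
    corpus_size = as.double(corpus_size),
    dialect = dialect,
    rejects = rejects %||% tibble(line = integer(), reason = character()),
    class = c("lexicon", class(entries))
  )
}

validate_entries <- function(entries) {
  if (any(!nzchar(entries$form) | is.na(entries$form))) {
    abort("Every entry must have a non-empty form after normalization.")
  }
  bad_pos <- setdiff(unique(entries$pos), c("noun", "adjective"))
  if (length(bad_pos) > 0L) {
    abort(sprintf("Invalid POS code(s): %s", paste(bad_pos, collapse = ", ")))
  }
  if (!all(entries$gender %in% GENDER_LEVELS)) {
    abort("Invalid gender code(s); expected F or M.")
  }
  if (!all(entries$number %in% c("SG", "PL"))) {
    abort("Invalid number code(s); expected SG or PL.")
  }
  if (any(is.na(entries$token_freq) | entries$token_freq < 0 |
          entries$token_freq != round(entries$token_freq))) {
    abort("`token_freq` must be a non-negative integer for every entry.")
  }
  dup <- duplicated(entries[, LEXICON_KEY])
  if (any(dup)) {
    abort(sprintf(
      "Duplicate (form, pos, gender, number, lemma) entries, e.g. '%s'.",
      entries$form[which(dup)[1L]]
    ))
  }
  invisible(entries)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf(
    "<lexicon> %d entries (%d noun, %d adjective), corpus size %s\n",
    nrow(x), sum(x$pos == "noun"), sum(x$pos == "adjective"),
    format(attr(x, "corpus_size"), big.mark = ",", scientific = FALSE)
  ))
  NextMethod()
}

#' Corpus size of a lexicon
#' @param x a lexicon.
#' @return the total token count of the source corpus.
#' @export
corpus_size <- function(x) attr(x, "corpus_size")

#' Rejected-row report of a lexicon read
#' @param x a lexicon returned by [read_lexicon()].
#' @return tibble with columns `line` and `reason`.
#' @export
lexicon_rejects <- function(x) attr(x, "rejects")

#' Read an annotated word-form frequency lexicon
#'
#' Reads a UTF-8 tab-separated file with a header row, one row per inflected
#' form, and validates every row. Rows with an unknown POS/gender/number
#' code or a malformed frequency are rejected (never silently dropped): they
#' are counted in the rejection report available via [lexicon_rejects()].
#' Rows that are duplicates on the full entry key have their frequencies
#' summed with a warning, as sharded corpus exports commonly split counts.
#'
#' @param path path to the TSV file.
#' @param corpus_size positive number, total tokens of the source corpus.
#' @param dialect name of a built-in dialect (see [lexicon_dialects]) or a
#'   named character vector mapping semantic fields to column names.
#' @param max_reject_frac abort when more than this fraction of rows is
#'   rejected (signals a dialect mismatch rather than a few bad rows).
#' @return a [lexicon()].
#' @export
read_lexicon <- function(path, corpus_size, dialect = "flexit",
                         max_reject_frac = 0.5) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  map <- resolve_dialect(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  required <- c("form", "lemma", "pos", "gender", "number", "freq")
  for (field in required) {
    if (!map[[field]] %in% names(raw)) {
      abort(sprintf("Required column '%s' (field %s) missing from %s",
                    map[[field]], field, path))
    }
  }
  df <- tibble(
    form = raw[[map[["form"]]]],
    lemma = raw[[map[["lemma"]]]],
    pos = normalize_pos(raw[[map[["pos"]]]]),
    gender = normalize_code(raw[[map[["gender"]]]]),
    number = normalize_code(raw[[map[["number"]]]]),
    freq_chr = trimws(raw[[map[["freq"]]]]),
    grade = if ("grade" %in% names(map) && map[["grade"]] %in% names(raw)) {
      g <- trimws(raw[[map[["grade"]]]])
      dplyr::if_else(nzchar(g), tolower(g), NA_character_)
    } else NA_character_,
    line = seq_len(nrow(raw)) + 1L  # +1 for the header row
  )

  freq_num <- suppressWarnings(as.numeric(df$freq_chr))
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(freq_num) | freq_num < 0 | freq_num != round(freq_num)] <-
    "malformed frequency (non-integer or negative)"
  reason[!df$pos %in% c("noun", "adjective")] <- "unknown POS code"
  reason[!df$gender %in% GENDER_LEVELS] <- "unknown gender code"
  reason[!df$number %in% c("SG", "PL")] <- "unknown number code"
  reason[!nzchar(df$form) | is.na(df$form)] <- "empty form"

  rejects <- tibble(line = df$line[!is.na(reason)], reason = reason[!is.na(reason)])
  if (nrow(df) > 0L && nrow(rejects) / nrow(df) > max_reject_frac) {
    abort(sprintf(
      "%d of %d rows rejected (> %.0f%%): the file likely does not match dialect '%s'.",
      nrow(rejects), nrow(df), 100 * max_reject_frac,
      if (is.character(dialect) && is.null(names(dialect))) dialect else "<custom>"
    ))
  }
  if (nrow(rejects) > 0L) {
    inform(sprintf("read_lexicon: rejected %d row(s); see lexicon_rejects().",
                   nrow(rejects)))
  }

  ok <- df[is.na(reason), ]
  ok$token_freq <- suppressWarnings(as.numeric(ok$freq_chr))
  ok$form <- normalize_form(ok$form)
  ok$lemma <- normalize_form(ok$lemma)

  dup <- duplicated(ok[, LEXICON_KEY])
  if (any(dup)) {
    warn(sprintf(
      "read_lexicon: %d duplicate key row(s); frequencies summed.", sum(dup)
    ))
    ok <- ok |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(LEXICON_KEY, "grade")))) |>
      dplyr::summarise(token_freq = sum(.data$token_freq), .groups = "drop")
  }
  lexicon(
    ok[, c(LEXICON_KEY, "token_freq", "grade")],
    corpus_size = corpus_size,
    dialect = if (is.character(dialect) && is.null(names(dialect))) dialect else "custom",
    rejects = rejects
  )
}

#' Merge a frequency table with a morphological annotation list
#'
#' Joins corpus token frequencies, keyed by (form, POS), with a
#' finer-grained annotation list carrying lemma, gender, number and grade.
#' A form with k annotation rows within one POS yields k entries that all
#' carry the same, undivided token frequency: the corpus tagger cannot
#' split a homograph's occurrences across feature values, which is exactly
#' the ambiguity that the counting policy of [apply_counting_policy()]
#' handles downstream.
#'
#' @param freq_table tibble with columns `form`, `pos`, `token_freq`; one
#'   row per (form, pos).
#' @param annotation tibble with columns `form`, `pos`, `lemma`, `gender`,
#'   `number` and optionally `grade`.
#' @param corpus_size positive number, total tokens of the source corpus.
#' @return a [lexicon()]; unmatched rows from either side are attached as
#'   attributes `unmatched_freq` and `unmatched_annotation`.
#' @export
merge_frequency_annotation <- function(freq_table, annotation, corpus_size) {
  freq_table <- as_tibble(freq_table)
  annotation <- as_tibble(annotation)
  for (nm in c("form", "pos", "token_freq")) {
    if (!nm %in% names(freq_table)) abort(sprintf("freq_table lacks column '%s'", nm))
  }
  for (nm in c("form", "pos", "lemma", "gender", "number")) {
    if (!nm %in% names(annotation)) abort(sprintf("annotation lacks column '%s'", nm))
  }
  freq_table$form <- normalize_form(freq_table$form)
  freq_table$pos <- normalize_pos(freq_table$pos)
  annotation$form <- normalize_form(annotation$form)
  annotation$pos <- normalize_pos(annotation$pos)
  if (anyDuplicated(freq_table[, c("form", "pos")]) > 0L) {
    abort("freq_table has duplicate (form, pos) rows; aggregate them first.")
  }
  if (!"grade" %in% names(annotation)) annotation$grade <- NA_character_

  joined <- dplyr::inner_join(annotation, freq_table, by = c("form", "pos"))
  unmatched_freq <- dplyr::anti_join(freq_table, annotation, by = c("form", "pos"))
  unmatched_annot <- dplyr::anti_join(annotation, freq_table, by = c("form", "pos"))
  if (nrow(joined) == 0L) {
    abort(sprintf(
      "Empty join: %d frequency rows and %d annotation rows share no (form, pos) key.",
      nrow(freq_table), nrow(annotation)
    ))
  }
  if (nrow(unmatched_freq) > 0L || nrow(unmatched_annot) > 0L) {
    inform(sprintf(
      "merge_frequency_annotation: %d frequency row(s) and %d annotation row(s) unmatched.",
      nrow(unmatched_freq), nrow(unmatched_annot)
    ))
  }
  out <- lexicon(
    joined[, c("form", "lemma", "pos", "gender", "number", "token_freq", "grade")],
    corpus_size = corpus_size, dialect = "merged"
  )
  attr(out, "unmatched_freq") <- unmatched_freq
  attr(out, "unmatched_annotation") <- unmatched_annot
  out
}

#' Standardize a raw token frequency to occurrences per million tokens
#'
#' @param token_freq numeric vector of raw corpus counts.
#' @param corpus_size positive number, total tokens of the source corpus.
#' @return `token_freq * 1e6 / corpus_size`.
#' @export
standardize_frequency <- function(token_freq, corpus_size) {
  if (length(corpus_size) != 1L || !is.numeric(corpus_size) ||
      is.na(corpus_size) || corpus_size <= 0) {
    abort("`corpus_size` must be a single positive number.")
  }
  if (any(token_freq < 0, na.rm = TRUE)) abort("`token_freq` must be non-negative.")
  token_freq * 1e6 / corpus_size
}

#' Write the full annotated lexicon table
#'
#' Writes the tab-separated database table: one row per entry, annotated
#' with its inflectional ending, its paradigm's declensional-class label,
#' and raw plus per-million frequency. Row order is deterministic
#' (pos, lemma, gender, number, form), so identical inputs produce
#' byte-identical files. Re-reading the file with
#' `read_lexicon(dialect = "flexit")` restores an equal lexicon.
#'
#' @param lexicon a [lexicon()].
#' @param paradigms the paradigm table from [build_paradigms()] covering
#'   every lemma of the lexicon.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flexit_table <- function(lexicon, paradigms, path) {
  entries <- as_tibble(lexicon)
  cells <- paradigm_cells(paradigms)
  out <- dplyr::left_join(
    entries,
    cells[, c("pos", "lemma", "gender", "number", "form", "class")],
    by = c("pos", "lemma", "gender", "number", "form")
  )
  if (nrow(entries) > 0L && anyNA(out$class)) {
    missing_lemma <- unique(out$lemma[is.na(out$class)])
    abort(sprintf("No class label available for lemma(s): %s",
                  paste(utils::head(missing_lemma, 5L), collapse = ", ")))
  }
  out$ending <- if (nrow(out) > 0L) extract_ending(out$form) else character()
  out$raw_freq <- out$token_freq
  out$freq_per_million <- standardize_frequency(out$token_freq, corpus_size(lexicon))
  out$grade <- dplyr::coalesce(out$grade, "")
  out <- dplyr::arrange(out, .data$pos, .data$lemma, .data$gender,
                        .data$number, .data$form)
  cols <- c("form", "lemma", "pos", "gender", "number", "ending", "class",
            "grade", "raw_freq", "freq_per_million")
  readr::write_tsv(out[, cols], path, progress = FALSE)
  invisible(path)
}
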