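#' Tokenize a text into lowercase word tokens
#'
#' Splits a single text into lowercase tokens. A token is a maximal run of
#' Unicode letters/digits, with internal apostrophes (straight or curly) and
#' hyphens retained, so "don't" and "long-term" are single tokens. All
#' punctuation and whitespace act as separators. No stemming is applied: the
#' BA lexicon enumerates inflected forms explicitly, and keeping surface forms
#' keeps the dictionary consistent with the texts being scored.
#'
#' @param text A single character string (NA is treated as empty).
#' @return A character vector of lowercase tokens (length 0 for empty input).
#' @examples
#' tokenize("I, me. My!")
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  tokenize_many(text)[[1L]]
}

# Vectorised tokenizer: list of token vectors, one per input string.
tokenize_many <- function(texts) {
  texts <- ifelse(is.na(texts), "", texts)
  out <- stringi::stri_extract_all_regex(
    stringi::stri_trans_tolower(texts),
    "[\\p{L}\\p{N}]+(?:['\\u2019-][\\p{L}\\p{N}]+)*",
    omit_no_match = TRUE
  )
  lapply(out, function(x) if (length(x) == 0L) character(0) else x)
}

study_weeks <- function() -3:11

phq_schedule <- function() c(0L, 3L, 6L, 9L, 12L)

#' Read a chat log
#'
#' Reads one message record per row from a delimited file (CSV/TSV with a
#' header) or a JSON-lines file. Required fields are `patient_id`, `text`,
#' and either `week` (integer study week) or `date`; dates are converted to
#' weeks as `floor((date - baseline_date) / 7)` using a per-patient or global
#' baseline date.
#'
#' @param path Path to the file.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"jsonl"`. `"auto"` picks
#'   by file extension.
#' @param baseline_date A `Date` (or string), or a named vector of dates keyed
#'   by patient_id, used only when the file has a `date` column.
#' @return A tibble of messages with columns `patient_id`, `week`, `text`.
#' @export
read_chat_log <- function(path, format = c("auto", "csv", "tsv", "jsonl"),
                          baseline_date = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("chat log file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", jsonl = "jsonl", ndjson = "jsonl", "csv")
  }
  raw <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE),
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE),
    jsonl = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
      dplyr::bind_rows(lapply(rows, function(r) tibble::as_tibble(lapply(r, as.character))))
    }
  )
  validate_messages(raw, baseline_date = baseline_date, source = path)
}

# Shared schema/row validation for chat logs; rows are 1-based data rows.
validate_messages <- function(raw, baseline_date = NULL, source = "<data>") {
  has_week <- "week" %in% names(raw)
  has_date <- "date" %in% names(raw)
  required <- c("patient_id", "text")
  missing_cols <- setdiff(required, names(raw))
  if (!has_week && !has_date) missing_cols <- c(missing_cols, "week|date")
  if (length(missing_cols) > 0L) {
    stop("chat log ", source, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_id <- which(is.na(raw$patient_id) | !nzchar(trimws(raw$patient_id)))
  if (length(bad_id) > 0L) {
    stop("chat log ", source, ": missing patient_id in row(s) ",
         paste(head(bad_id, 10L), collapse = ", "))
  }
  if (has_week) {
    week <- suppressWarnings(as.integer(raw$week))
    bad_week <- which(is.na(week))
    if (length(bad_week) > 0L) {
      stop("chat log ", source, ": unparseable week in row(s) ",
           paste(head(bad_week, 10L), collapse = ", "))
    }
  } else {
    date <- suppressWarnings(as.Date(raw$date))
    bad_date <- which(is.na(date))
    if (length(bad_date) > 0L) {
      stop("chat log ", source, ": unparseable date in row(s) ",
           paste(head(bad_date, 10L), collapse = ", "))
    }
    if (is.null(baseline_date)) {
      stop("chat log ", source, " uses dates; supply baseline_date to convert to weeks")
    }
    base <- if (!is.null(names(baseline_date))) {
      b <- as.Date(baseline_date)[match(raw$patient_id, names(baseline_date))]
      if (anyNA(b)) stop("baseline_date missing for patient(s): ",
                         paste(unique(raw$patient_id[is.na(b)]), collapse = ", "))
      b
    } else {
      as.Date(baseline_date)
    }
    week <- as.integer(floor(as.numeric(date - base) / 7))
  }
  text <- raw$text
  text[is.na(text)] <- ""
  tibble::tibble(
    patient_id = as.character(raw$patient_id),
    week = week,
    text = as.character(text)
  )
}

#' Write a chat log to CSV
#'
#' @param messages A message tibble (`patient_id`, `week`, `text`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chat_log <- function(messages, path) {
  readr::write_csv(messages[, c("patient_id", "week", "text")], path, progress = FALSE)
  invisible(path)
}

#' Read PHQ-9 assessments
#'
#' Reads a CSV with columns `patient_id`, `week`, `phq9`. Scores must be
#' integers in 0-27 and weeks must lie on the assessment schedule
#' (0, 3, 6, 9, 12): the questionnaire is administered at baseline and every
#' 3 weeks during the 12-week course.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `patient_id`, `week`, `phq9`.
#' @export
read_phq <- function(path) {
  if (!file.exists(path)) stop("PHQ file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c("patient_id", "week", "phq9"), names(raw))
  if (length(missing_cols) > 0L) {
    stop("PHQ file is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(
    patient_id = as.character(raw$patient_id),
    week = suppressWarnings(as.integer(raw$week)),
    phq9 = suppressWarnings(as.integer(raw$phq9))
  )
  validate_assessments(out)
}

validate_assessments <- function(assessments) {
  bad_week <- which(is.na(assessments$week) | !(assessments$week %in% phq_schedule()))
  if (length(bad_week) > 0L) {
    stop("PHQ assessments: week outside schedule {0,3,6,9,12} in row(s) ",
         paste(head(bad_week, 10L), collapse = ", "))
  }
  bad_score <- which(is.na(assessments$phq9) | assessments$phq9 < 0L | assessments$phq9 > 27L)
  if (length(bad_score) > 0L) {
    stop("PHQ assessments: score outside [0,27] in row(s) ",
         paste(head(bad_score, 10L), collapse = ", "))
  }
  assessments
}

#' Pool messages into per-assessment documents
#'
#' For each PHQ-9 assessment at week `w`, concatenates (in input order) all of
#' that patient's messages from the two preceding weeks, `w-2` and `w-1` — the
#' period the questionnaire asks respondents to reflect on. One document is
#' produced per (patient, assessment); assessments with no messages in the
#' window yield an empty, flagged document (token_count 0) so joins with PHQ
#' scores stay aligned. Downstream analyses drop the empty rows.
#'
#' @param messages Message tibble (`patient_id`, `week`, `text`).
#' @param assessments Assessment tibble (`patient_id`, `week`, `phq9`).
#' @return A tibble of pooled documents: `patient_id`, `window_label`
#'   (assessment week), `phq9`, `tokens` (list column), `token_count`,
#'   `is_empty`.
#' @export
pool_by_assessment <- function(messages, assessments) {
  assessments <- validate_assessments(assessments)
  toks <- tokenize_many(messages$text)
  out <- lapply(seq_len(nrow(assessments)), function(i) {
    pid <- assessments$patient_id[i]
    w <- assessments$week[i]
    sel <- which(messages$patient_id == pid &
                   messages$week >= (w - 2L) & messages$week <= (w - 1L))
    tk <- if (length(sel)) unlist(toks[sel], use.names = FALSE) else character(0)
    tibble::tibble(
      patient_id = pid, window_label = w, phq9 = assessments$phq9[i],
      tokens = list(tk), token_count = length(tk), is_empty = length(tk) == 0L
    )
  })
  dplyr::bind_rows(out)
}

#' Pool messages into per-week documents
#'
#' Concatenates each patient's messages within a calendar study week (weeks
#' -3 through 11, up to 15 per patient) into a single document, preserving
#' input order. Weeks outside the study range are dropped with a warning.
#' Only (patient, week) pairs with at least one message yield a document.
#'
#' @param messages Message tibble (`patient_id`, `week`, `text`).
#' @return A tibble of pooled documents: `patient_id`, `window_label` (week),
#'   `tokens` (list column), `token_count`, `is_empty`.
#' @export
pool_by_week <- function(messages) {
  in_range <- messages$week >= min(study_weeks()) & messages$week <= max(study_weeks())
  if (any(!in_range)) {
    warning(sum(!in_range), " message(s) outside study weeks [-3, 11] dropped")
    messages <- messages[in_range, , drop = FALSE]
  }
  if (nrow(messages) == 0L) {
    return(tibble::tibble(patient_id = character(0), window_label = integer(0),
                          tokens = list(), token_count = integer(0),
                          is_empty = logical(0)))
  }
  toks <- tokenize_many(messages$text)
  key <- paste(messages$patient_id, messages$week, sep = "\r")
  ord <- order(match(key, unique(key)))  # stable: groups in first-appearance order
  grouped <- split(toks[ord], factor(key[ord], levels = unique(key)))
  ids <- strsplit(names(grouped), "\r", fixed = TRUE)
  tk <- lapply(grouped, function(g) unlist(g, use.names = FALSE))
  tibble::tibble(
    patient_id = vapply(ids, `[`, "", 1L),
    window_label = as.integer(vapply(ids, `[`, "", 2L)),
    tokens = unname(tk),
    token_count = vapply(tk, length, 1L),
    is_empty = vapply(tk, length, 1L) == 0L
  ) |>
    dplyr::arrange(.data$patient_id, .data$window_label)
}
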