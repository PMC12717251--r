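#' Clinical record sections, anonymization and token counting
#'
#' A `clinical_record` holds the four core data components extracted per
#' case: general patient information, chronological postoperative notes,
#' abnormal laboratory results, and examination reports, plus any structured
#' direct identifiers slated for removal.
#'
#' @name clinical-records
NULL

.record_sections <- c("postop_notes", "abnormal_labs", "exam_reports")

.section_titles <- c(
  general_info = "General Information",
  postop_notes = "Postoperative Medical Records",
  abnormal_labs = "Abnormal Test Results",
  exam_reports = "Examination Results"
)

.dated_tbl <- function(x, section) {
  if (is.null(x)) {
    return(tibble::tibble(date = as.Date(character()), text = character()))
  }
  x <- tibble::as_tibble(x)
  if (!all(c("date", "text") %in% names(x))) {
    stop("section '", section, "' needs columns 'date' and 'text'",
         call. = FALSE)
  }
  parsed <- tryCatch(as.Date(x$date), error = function(e) NULL)
  if (is.null(parsed) || anyNA(parsed)) {
    bad <- if (is.null(parsed)) x$date else x$date[is.na(parsed)]
    stop("non-parseable date in section '", section, "': ",
         paste(utils::head(as.character(bad), 3), collapse = ", "),
         call. = FALSE)
  }
  x$date <- parsed
  if (is.unsorted(x$date)) {
    stop("dated entries in section '", section,
         "' must be sorted non-decreasing by date", call. = FALSE)
  }
  x[, c("date", "text")]
}

#' Construct a clinical record
#'
#' @param general_info free-text block of demographic and procedural
#'   information.
#' @param postop_notes,abnormal_labs,exam_reports data frames with columns
#'   `date` (ISO-8601 calendar date) and `text`, sorted non-decreasing by
#'   date.
#' @param identifiers character vector of structured direct identifiers
#'   (name, record number, ...) to be removed at anonymization.
#' @return object of class `clinical_record`.
#' @examples
#' rec <- clinical_record(
#'   general_info = "64-year-old, gastrectomy",
#'   postop_notes = data.frame(date = c("2024-03-02", "2024-03-04"),
#'                             text = c("day 1 stable", "fever 38.5")),
#'   identifiers = c("MRN 12345")
#' )
#' @export
clinical_record <- function(general_info = "", postop_notes = NULL,
                            abnormal_labs = NULL, exam_reports = NULL,
                            identifiers = character()) {
  structure(
    list(
      general_info = as.character(general_info),
      postop_notes = .dated_tbl(postop_notes, "postop_notes"),
      abnormal_labs = .dated_tbl(abnormal_labs, "abnormal_labs"),
      exam_reports = .dated_tbl(exam_reports, "exam_reports"),
      identifiers = as.character(identifiers)
    ),
    class = "clinical_record"
  )
}

#' @export
print.clinical_record <- function(x, ...) {
  n_dated <- sum(vapply(.record_sections, function(s) nrow(x[[s]]), integer(1)))
  cat("<clinical_record> ", n_dated, " dated entries, ",
      length(x$identifiers), " identifiers\n", sep = "")
  invisible(x)
}

#' Time-shift anonymization
#'
#' Applies one per-patient random temporal offset (in days) uniformly to
#' every dated entry in every section, preserving all relative temporal
#' relationships and intervals between clinical events, and removes all
#' structured direct identifiers. Deterministic given `seed`; idempotent on
#' identifiers (a second application with offset 0 changes nothing further).
#'
#' @param record a [clinical_record()].
#' @param offset_days explicit integer offset; if `NULL`, drawn uniformly
#'   from \[-3650, 3650\] using `seed`.
#' @param seed integer seed used when `offset_days` is `NULL`.
#' @return the anonymized record, with the applied offset attached as
#'   attribute `offset_days`.
#' @export
timeshift_anonymize <- function(record, offset_days = NULL, seed = NULL) {
  stopifnot(inherits(record, "clinical_record"))
  if (is.null(offset_days)) {
    if (is.null(seed)) {
      stop("provide offset_days or a seed to draw one", call. = FALSE)
    }
    offset_days <- .with_seed(seed, sample(-3650:3650, 1))
  }
  offset_days <- as.integer(offset_days)
  for (s in .record_sections) {
    record[[s]]$date <- record[[s]]$date + offset_days
  }
  record$identifiers <- character()
  attr(record, "offset_days") <- offset_days
  record
}

#' Assemble a record into standardized markdown
#'
#' Renders the four section headers in fixed order (general information,
#' postoperative medical records, abnormal test results, examination
#' results), dated entries as `## YYYY-MM-DD` sub-headers in chronological
#' order. Empty sections render as a bare header. Deterministic and
#' order-stable.
#'
#' @param record a [clinical_record()].
#' @return a single markdown string.
#' @export
assemble_markdown <- function(record) {
  stopifnot(inherits(record, "clinical_record"))
  parts <- c(paste0("# ", .section_titles[["general_info"]]))
  if (nzchar(record$general_info)) parts <- c(parts, record$general_info)
  for (s in .record_sections) {
    parts <- c(parts, paste0("# ", .section_titles[[s]]))
    tbl <- record[[s]]
    for (i in seq_len(nrow(tbl))) {
      parts <- c(parts, paste0("## ", format(tbl$date[i], "%Y-%m-%d")),
                 tbl$text[i])
    }
  }
  paste(parts, collapse = "\n\n")
}

#' Parse standardized record markdown back into sections
#'
#' Inverse of [assemble_markdown()] for well-formed output; used to verify
#' the assembly round-trips losslessly.
#'
#' @param text markdown produced by [assemble_markdown()].
#' @return a [clinical_record()] (with no identifiers: they are not rendered).
#' @export
parse_markdown_record <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  section_of <- stats::setNames(names(.section_titles),
                                paste0("# ", .section_titles))
  current <- NA_character_
  current_date <- NA_character_
  general <- character()
  dated <- list(postop_notes = list(), abnormal_labs = list(),
                exam_reports = list())
  for (ln in lines) {
    if (ln %in% names(section_of)) {
      current <- section_of[[ln]]
      current_date <- NA_character_
    } else if (grepl("^## \\d{4}-\\d{2}-\\d{2}$", ln)) {
      current_date <- sub("^## ", "", ln)
    } else if (nzchar(ln)) {
      if (is.na(current)) next
      if (current == "general_info") {
        general <- c(general, ln)
      } else if (!is.na(current_date)) {
        dated[[current]] <- c(dated[[current]],
                              list(list(date = current_date, text = ln)))
      }
    }
  }
  to_tbl <- function(entries) {
    if (length(entries) == 0) return(NULL)
    tibble::tibble(date = vapply(entries, `[[`, character(1), "date"),
                   text = vapply(entries, `[[`, character(1), "text"))
  }
  clinical_record(
    general_info = paste(general, collapse = "\n\n"),
    postop_notes = to_tbl(dated$postop_notes),
    abnormal_labs = to_tbl(dated$abnormal_labs),
    exam_reports = to_tbl(dated$exam_reports)
  )
}

#' Count tokens in a text
#'
#' The default heuristic counts whitespace-separated words, with each CJK
#' character counted as its own token — sufficient for a consistent ordering
#' of document lengths, which is all stratification needs. Any real tokenizer
#' can be plugged in as a function from text to a non-negative count.
#'
#' @param text character scalar.
#' @param tokenizer optional function `text -> integer count`; `NULL` selects
#'   the default heuristic.
#' @return non-negative integer, deterministic per (text, tokenizer).
#' @examples
#' count_tokens("fever on day two")  # 4
#' count_tokens("")                  # 0
#' @export
count_tokens <- function(text, tokenizer = NULL) {
  if (!is.null(tokenizer)) {
    n <- tokenizer(text)
    stopifnot(is.numeric(n), n >= 0)
    return(as.integer(n))
  }
  if (is.na(text) || !nzchar(text)) return(0L)
  cjk <- gregexpr("[\u4e00-\u9fff]", text)[[1]]
  n_cjk <- if (cjk[1] == -1) 0L else length(cjk)
  rest <- gsub("[\u4e00-\u9fff]", " ", text)
  words <- strsplit(trimws(rest), "\\s+")[[1]]
  n_words <- sum(nzchar(words))
  as.integer(n_cjk + n_words)
}

#' Build a schematic synthetic clinical record for a case
#'
#' Placeholder free text sufficient for markdown assembly, anonymization and
#' token counting; not realistic clinical prose.
#'
#' @param case_id case identifier woven into the text.
#' @param truth diagnosis tibble; mentioned in the notes so records are not
#'   content-free.
#' @param start_date admission date for the dated entries.
#' @param n_notes number of postoperative notes.
#' @param seed integer seed.
#' @return a [clinical_record()].
#' @export
synthetic_record <- function(case_id, truth = diagnosis_set(),
                             start_date = as.Date("2024-01-01"),
                             n_notes = 3, seed = 1L) {
  .with_seed(seed, {
    days <- sort(sample(0:20, n_notes))
    notes <- tibble::tibble(
      date = start_date + days,
      text = paste0("postoperative day ", days, ": ",
                    if (nrow(truth) > 0) {
                      paste("findings consistent with",
                            paste(truth$label, collapse = ", "))
                    } else "unremarkable course")
    )
    labs <- tibble::tibble(
      date = start_date + sort(sample(0:20, 2)),
      text = c("leukocytes elevated", "creatinine trending up")
    )
    exams <- tibble::tibble(date = start_date + sample(0:20, 1),
                            text = "imaging: no new collection")
    clinical_record(
      general_info = paste0("case ", case_id,
                            ": adult patient, major abdominal surgery"),
      postop_notes = notes, abnormal_labs = labs, exam_reports = exams,
      identifiers = c(paste0("MRN-", case_id), "attending: redacted")
    )
  })
}
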