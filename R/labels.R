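#' Complication label sets and diagnosis sets
#'
#' A label set is a tibble with one row per complication, columns `label`
#' (canonical name, unique) and `graded` (logical: does the label carry a
#' mild/moderate/severe grade). A diagnosis set is a tibble with columns
#' `label` and `grade`; the empty tibble represents the sentinel "no
#' postoperative complications".
#'
#' @name label-sets
NULL

#' Sentinel string for an empty diagnosis set
#'
#' The literal single-element response a predictor emits when no
#' complication is detected. Parsed back to an empty diagnosis set.
#' @export
SENTINEL_NO_COMPLICATIONS <- "no postoperative complications"

#' Severity grades, ordered from least to most severe
#' @export
SEVERITY_GRADES <- c("mild", "moderate", "severe")

.all_grades <- c(SEVERITY_GRADES, "unspecified")

#' Default perioperative complication label set
#'
#' The 20 named postoperative complications tracked by the dual-center
#' cohort tables, plus two configurable placeholder labels so that the full
#' standardized framework size of 22 is reached. The placeholders default to
#' zero prevalence and ungraded status; replace them with real names via the
#' `extra_labels` argument when a concrete 22-label criterion set is in use.
#'
#' @param extra_labels character vector of additional label names appended
#'   after the 20 named complications (default: two placeholders).
#' @param extra_graded logical vector, recycled, whether the extra labels are
#'   severity-graded.
#' @return tibble with columns `label` and `graded`.
#' @examples
#' default_label_set()
#' @export
default_label_set <- function(extra_labels = c("additional complication 1",
                                               "additional complication 2"),
                              extra_graded = FALSE) {
  named <- c(
    "paralytic ileus",
    "organ/space surgical site infection",
    "infection of unknown source",
    "myocardial injury after non-cardiac surgery",
    "anastomotic leakage",
    "pneumonia",
    "postoperative bleeding",
    "acute kidney injury",
    "superficial surgical site infection",
    "arrhythmia",
    "cardiogenic pulmonary edema",
    "deep vein thrombosis",
    "deep surgical site infection",
    "gastrointestinal bleeding",
    "delirium",
    "acute respiratory distress syndrome",
    "pulmonary embolism",
    "myocardial infarction",
    "bloodstream infection",
    "stroke"
  )
  out <- tibble::tibble(
    label = c(named, extra_labels),
    graded = c(rep(TRUE, length(named)),
               rep_len(as.logical(extra_graded), length(extra_labels)))
  )
  validate_label_set(out)
}

#' Validate a label set
#'
#' @param label_set tibble with columns `label`, `graded`.
#' @return the label set, invisibly unchanged, or an error.
#' @export
validate_label_set <- function(label_set) {
  if (!is.data.frame(label_set) ||
      !all(c("label", "graded") %in% names(label_set))) {
    stop("label_set must be a data frame with columns 'label' and 'graded'",
         call. = FALSE)
  }
  label_set <- tibble::as_tibble(label_set)
  if (nrow(label_set) == 0) stop("label_set must be non-empty", call. = FALSE)
  canon <- canonical_label(label_set$label)
  if (anyDuplicated(canon)) {
    stop("label_set contains duplicate labels: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "),
         call. = FALSE)
  }
  label_set
}

#' Canonicalize a complication label
#'
#' Case-insensitive exact matching after whitespace normalization; no fuzzy
#' matching, so near-miss names surface as unknown-label flags rather than
#' being silently absorbed.
#'
#' @param x character vector of label names.
#' @return canonical form: lower case, internal runs of whitespace collapsed,
#'   outer whitespace trimmed.
#' @export
canonical_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Construct a diagnosis set
#'
#' @param label character vector of complication labels.
#' @param grade character vector of severity grades
#'   (mild/moderate/severe/unspecified), recycled.
#' @return tibble with columns `label`, `grade`.
#' @examples
#' diagnosis_set("pneumonia", "moderate")
#' diagnosis_set()  # empty set (sentinel semantics)
#' @export
diagnosis_set <- function(label = character(), grade = "unspecified") {
  if (length(label) == 0) {
    return(tibble::tibble(label = character(), grade = character()))
  }
  grade <- rep_len(as.character(grade), length(label))
  bad <- setdiff(unique(grade), .all_grades)
  if (length(bad) > 0) {
    stop("unknown severity grade(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(label = as.character(label), grade = grade)
}

.empty_diagnoses <- function() diagnosis_set()

# rank for tie-breaking toward greater severity; unspecified ranks lowest
.grade_rank <- function(grade) {
  match(grade, c("unspecified", SEVERITY_GRADES))
}
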