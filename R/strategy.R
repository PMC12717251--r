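#' Comprehensive and targeted evaluation strategies
#'
#' The comprehensive strategy asks a predictor to assess every complication
#' in a single call; the targeted strategy decomposes the task into one
#' independent single-complication call per label and combines the verdicts
#' with two deterministic rules: (1) all-negative verdicts collapse to the
#' sentinel "no postoperative complications"; (2) a positive verdict for any
#' configured specific infectious complication suppresses "infection of
#' unknown source" to keep diagnoses mutually exclusive.
#'
#' @name strategies
NULL

#' Structured-output schema field names
#'
#' Key names of the JSON output dialect. Configurable because different
#' serving stacks emit slightly different keys; the defaults are a reasoning
#' field `think`, a list field `complications`, and per-item keys
#' `complication` and `severity`.
#'
#' @param think,complications,complication,severity field names.
#' @return named list of class `output_schema`.
#' @export
output_schema <- function(think = "think", complications = "complications",
                          complication = "complication",
                          severity = "severity") {
  structure(list(think = think, complications = complications,
                 complication = complication, severity = severity),
            class = "output_schema")
}

#' Serialize a diagnosis set as structured model output
#'
#' Inverse of [parse_model_output()] on well-formed records. An empty
#' diagnosis set serializes as the single-element sentinel response.
#'
#' @param diagnoses diagnosis tibble (`label`, `grade`).
#' @param think optional reasoning text included under the schema's think key.
#' @param schema an [output_schema()].
#' @return a JSON string.
#' @export
serialize_model_output <- function(diagnoses, think = NULL,
                                   schema = output_schema()) {
  body <- list()
  if (!is.null(think)) body[[schema$think]] <- jsonlite::unbox(think)
  items <- if (nrow(diagnoses) == 0) {
    list(stats::setNames(
      list(jsonlite::unbox(SENTINEL_NO_COMPLICATIONS)), schema$complication
    ))
  } else {
    lapply(seq_len(nrow(diagnoses)), function(i) {
      stats::setNames(
        list(jsonlite::unbox(diagnoses$label[i]),
             jsonlite::unbox(diagnoses$grade[i])),
        c(schema$complication, schema$severity)
      )
    })
  }
  body[[schema$complications]] <- items
  as.character(jsonlite::toJSON(body, auto_unbox = FALSE))
}

#' Parse raw structured model output
#'
#' Validates a raw text record against the structured-output schema. The
#' sentinel maps to an empty diagnosis set; unknown label names and grades
#' are flagged, never fatal; structural failures yield `status = "failed"`
#' with a diagnostic message rather than an error.
#'
#' @param raw_text raw model output text.
#' @param expect_think require a non-empty reasoning field.
#' @param schema an [output_schema()].
#' @param label_set optional label set; labels outside it are reported in
#'   `unknown_labels` (and excluded from `diagnoses`).
#' @return list with `diagnoses` (tibble), `think` (character or `NA`),
#'   `status` ("ok" or "failed"), `message`, `unknown_labels`, `sentinel`
#'   (logical: was the sentinel response seen).
#' @examples
#' parse_model_output('{"complications":[{"complication":"pneumonia",
#'                      "severity":"moderate"}]}')
#' @export
parse_model_output <- function(raw_text, expect_think = FALSE,
                               schema = output_schema(), label_set = NULL) {
  fail <- function(msg) {
    list(diagnoses = diagnosis_set(), think = NA_character_,
         status = "failed", message = msg, unknown_labels = character(),
         sentinel = FALSE)
  }
  if (length(raw_text) != 1 || is.na(raw_text) || !nzchar(raw_text)) {
    return(fail("empty output"))
  }
  parsed <- tryCatch(jsonlite::fromJSON(raw_text, simplifyVector = FALSE),
                     error = function(e) NULL)
  if (is.null(parsed) || !is.list(parsed)) {
    return(fail("not valid JSON"))
  }
  items <- parsed[[schema$complications]]
  if (is.null(items) || !is.list(items)) {
    return(fail(paste0("missing '", schema$complications, "' list")))
  }
  think <- parsed[[schema$think]]
  think <- if (is.null(think)) NA_character_ else as.character(think)[1]
  if (expect_think && (is.na(think) || !nzchar(think))) {
    return(fail("reasoning field required but absent"))
  }

  labels <- character(); grades <- character(); sentinel <- FALSE
  for (it in items) {
    nm <- if (is.list(it)) it[[schema$complication]] else it
    if (is.null(nm) || !is.character(nm <- as.character(nm)[1])) {
      return(fail("complication entry without a label"))
    }
    if (canonical_label(nm) == canonical_label(SENTINEL_NO_COMPLICATIONS)) {
      sentinel <- TRUE
      next
    }
    gr <- if (is.list(it)) it[[schema$severity]] else NULL
    gr <- if (is.null(gr)) "unspecified" else tolower(trimws(as.character(gr)[1]))
    if (!gr %in% .all_grades) gr <- "unspecified"
    labels <- c(labels, nm); grades <- c(grades, gr)
  }
  unknown <- character()
  if (!is.null(label_set) && length(labels) > 0) {
    known <- canonical_label(label_set$label)
    is_known <- canonical_label(labels) %in% known
    unknown <- labels[!is_known]
    labels <- labels[is_known]; grades <- grades[is_known]
  }
  list(diagnoses = diagnosis_set(labels, grades), think = think,
       status = "ok", message = NA_character_, unknown_labels = unknown,
       sentinel = sentinel && length(labels) == 0)
}

#' Decompose a case into targeted single-complication task units
#'
#' One task unit per label in the label set, each carrying the identical
#' record text and one distinct target label, so a predictor evaluates one
#' specific complication per inference call.
#'
#' @param case_id case identifier.
#' @param record_text the case's assembled record text (shared by all units).
#' @param label_set label set tibble.
#' @return tibble with columns `case_id`, `target_label`, `record_text`;
#'   exactly `nrow(label_set)` rows.
#' @export
decompose_targeted <- function(case_id, record_text, label_set) {
  label_set <- validate_label_set(label_set)
  tibble::tibble(case_id = case_id, target_label = label_set$label,
                 record_text = record_text)
}

#' Default specific infectious complications for the exclusion rule
#'
#' The configured subset whose positive identification suppresses a
#' co-occurring "infection of unknown source" diagnosis.
#' @return character vector of label names.
#' @export
default_specific_infections <- function() {
  c("pneumonia",
    "superficial surgical site infection",
    "deep surgical site infection",
    "organ/space surgical site infection",
    "bloodstream infection")
}

#' Aggregate targeted per-label verdicts into a final diagnosis set
#'
#' Applies the two final-output rules of the targeted strategy:
#' all-negative verdicts yield the sentinel (an empty diagnosis set with
#' attribute `sentinel = TRUE`); a positive verdict on any configured
#' specific infectious complication removes "infection of unknown source"
#' even if its own verdict was positive.
#'
#' @param verdicts tibble with columns `label`, `present` (logical), `grade`;
#'   exactly one row per label in `label_set`.
#' @param label_set label set tibble.
#' @param specific_infections labels whose presence suppresses the
#'   unknown-source infection diagnosis.
#' @param unknown_source_label the label suppressed by rule 2.
#' @return diagnosis tibble of the positive verdicts, with attribute
#'   `sentinel` set when all verdicts were negative.
#' @export
aggregate_targeted <- function(verdicts, label_set,
                               specific_infections = default_specific_infections(),
                               unknown_source_label = "infection of unknown source") {
  label_set <- validate_label_set(label_set)
  missing <- setdiff(canonical_label(label_set$label),
                     canonical_label(verdicts$label))
  if (length(missing) > 0) {
    stop("missing verdicts for labels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pos <- verdicts[verdicts$present, , drop = FALSE]
  if (nrow(pos) == 0) {
    out <- diagnosis_set()
    attr(out, "sentinel") <- TRUE
    return(out)
  }
  has_specific <- any(canonical_label(pos$label) %in%
                        canonical_label(specific_infections))
  if (has_specific) {
    pos <- pos[canonical_label(pos$label) !=
                 canonical_label(unknown_source_label), , drop = FALSE]
  }
  out <- diagnosis_set(pos$label, pos$grade)
  attr(out, "sentinel") <- FALSE
  out
}

#' Run the comprehensive strategy on one case
#'
#' One predictor call assessing all labels simultaneously; the raw output is
#' parsed against the structured-output schema, retrying up to `retries`
#' times on parse failure. A final failure is recorded (empty prediction,
#' `parse_failed = TRUE`), never silent.
#'
#' @param case_id case identifier.
#' @param record_text assembled record text.
#' @param predictor function `(record_text, labels, mode, cot) -> raw text`;
#'   stateless with respect to evaluation bookkeeping, may be stochastic.
#' @param label_set label set tibble.
#' @param cot ask the predictor for chain-of-thought output and require the
#'   reasoning field when parsing.
#' @param retries parse-failure retry budget (additional predictor calls).
#' @param schema an [output_schema()].
#' @return list with `diagnoses`, `sentinel`, `parse_failed`, `n_calls`,
#'   `unknown_labels`.
#' @export
run_comprehensive <- function(case_id, record_text, predictor, label_set,
                              cot = FALSE, retries = 2,
                              schema = output_schema()) {
  label_set <- validate_label_set(label_set)
  n_calls <- 0
  res <- NULL
  for (attempt in seq_len(retries + 1)) {
    raw <- predictor(record_text, label_set$label, "comprehensive", cot)
    n_calls <- n_calls + 1
    res <- parse_model_output(raw, expect_think = cot, schema = schema,
                              label_set = label_set)
    if (res$status == "ok") break
  }
  list(diagnoses = res$diagnoses,
       sentinel = isTRUE(res$sentinel),
       parse_failed = res$status != "ok",
       n_calls = n_calls,
       unknown_labels = res$unknown_labels)
}

#' Run the targeted strategy on one case
#'
#' One predictor call per label (plus retries), each parsed as a
#' single-complication verdict: the target label is "present" when it appears
#' in the parsed diagnosis list. A unit whose output cannot be parsed within
#' the retry budget is recorded as a negative verdict with a failure flag, so
#' aggregation stays total and failures stay auditable. Verdicts are combined
#' with [aggregate_targeted()].
#'
#' @inheritParams run_comprehensive
#' @param specific_infections see [aggregate_targeted()].
#' @return list with `diagnoses`, `sentinel`, `verdicts` (per-label tibble
#'   including `parse_failed`), `n_calls`.
#' @export
run_targeted <- function(case_id, record_text, predictor, label_set,
                         cot = FALSE, retries = 2, schema = output_schema(),
                         specific_infections = default_specific_infections()) {
  label_set <- validate_label_set(label_set)
  units <- decompose_targeted(case_id, record_text, label_set)
  n_calls <- 0
  verdicts <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    target <- units$target_label[i]
    unit_labels <- label_set[canonical_label(label_set$label) ==
                               canonical_label(target), , drop = FALSE]
    res <- NULL
    for (attempt in seq_len(retries + 1)) {
      raw <- predictor(units$record_text[i], target, "targeted", cot)
      n_calls <<- n_calls + 1
      res <- parse_model_output(raw, expect_think = cot, schema = schema,
                                label_set = unit_labels)
      if (res$status == "ok") break
    }
    if (res$status != "ok") {
      return(tibble::tibble(label = target, present = FALSE,
                            grade = "unspecified", parse_failed = TRUE))
    }
    hit <- canonical_label(res$diagnoses$label) == canonical_label(target)
    tibble::tibble(
      label = target,
      present = any(hit),
      grade = if (any(hit)) res$diagnoses$grade[which(hit)[1]] else "unspecified",
      parse_failed = FALSE
    )
  })
  final <- aggregate_targeted(verdicts, label_set,
                              specific_infections = specific_infections)
  list(diagnoses = final, sentinel = isTRUE(attr(final, "sentinel")),
       verdicts = verdicts, n_calls = n_calls)
}

#' Expand a cohort into per-label training examples
#'
#' The targeted strategy's training expansion: every (case, label) pair
#' becomes one single-complication example whose verdict and grade are read
#' off the case's true diagnosis set, so a cohort of `n` cases and `L` labels
#' yields exactly `n * L` examples (146 cases and 22 labels give 3212).
#'
#' @param cohort tibble from [generate_cohort()] (or any tibble with
#'   `case_id` and a `truth` list-column).
#' @param label_set label set tibble; defaults to the cohort's.
#' @return tibble with columns `case_id`, `target_label`, `present`, `grade`,
#'   one row per case x label.
#' @export
expand_training_examples <- function(cohort, label_set = NULL) {
  if (is.null(label_set)) label_set <- cohort_label_set(cohort)
  label_set <- validate_label_set(label_set)
  canon <- canonical_label(label_set$label)
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    tr <- cohort$truth[[i]]
    idx <- match(canon, canonical_label(tr$label))
    tibble::tibble(
      case_id = cohort$case_id[i],
      target_label = label_set$label,
      present = !is.na(idx),
      grade = ifelse(is.na(idx), "unspecified", tr$grade[idx])
    )
  })
}

#' A deterministic truth-echo predictor for a cohort
#'
#' Returns a predictor closure that answers from the cohort's true diagnosis
#' sets: in comprehensive mode it emits the full set (or the sentinel); in
#' targeted mode it emits the target label iff truly present. Useful as the
#' reference backend for strategy-equivalence checks and pipeline tests.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param schema an [output_schema()].
#' @return function `(record_text, labels, mode, cot) -> raw text`; record
#'   text must start with the case id (as produced by [case_record_text()]).
#' @export
truth_echo_predictor <- function(cohort, schema = output_schema()) {
  truth_by_id <- stats::setNames(cohort$truth, cohort$case_id)
  function(record_text, labels, mode, cot) {
    case_id <- sub("^(\\S+).*$", "\\1", record_text)
    tr <- truth_by_id[[case_id]]
    if (is.null(tr)) stop("unknown case in record text: ", case_id)
    out <- if (identical(mode, "targeted")) {
      hit <- canonical_label(tr$label) %in% canonical_label(labels)
      tr[hit, , drop = FALSE]
    } else {
      tr
    }
    think <- if (isTRUE(cot)) "verdict read from the reference standard" else NULL
    serialize_model_output(out, think = think, schema = schema)
  }
}

#' Minimal record text for a case
#'
#' The case id followed by a schematic body; enough for predictors keyed by
#' case id (e.g. [truth_echo_predictor()]) and for token accounting in run
#' manifests.
#'
#' @param cohort cohort tibble.
#' @return character vector of record texts, one per case.
#' @export
case_record_text <- function(cohort) {
  paste0(cohort$case_id, " synthetic clinical record (",
         cohort$token_count, " tokens)")
}

#' Run a strategy over a whole cohort, with a run manifest
#'
#' Applies [run_comprehensive()] or [run_targeted()] to every case and
#' returns both the predictions (in the standard predictions-table shape)
#' and a manifest with one row per (case, strategy, run) recording parse
#' status and predictor call count, the audit trail for the parse-failure
#' conventions and for token/call accounting.
#'
#' @param cohort cohort tibble.
#' @param predictor predictor contract function, see [run_comprehensive()].
#' @param strategy `"comprehensive"` or `"targeted"`.
#' @param run run index recorded in the output (call repeatedly for
#'   repeated inference runs of a stochastic predictor).
#' @param source identifier stored in the predictions' `source` column.
#' @param ... passed through to the per-case runner (`cot`, `retries`,
#'   `schema`, `specific_infections`).
#' @return list with `predictions` (tibble `case_id`, `source`, `run`,
#'   `diagnoses`) and `manifest` (tibble `case_id`, `strategy`, `run`,
#'   `parse_failed`, `n_failed_units`, `n_calls`, `sentinel`).
#' @export
run_strategy <- function(cohort, predictor,
                         strategy = c("comprehensive", "targeted"),
                         run = 1L, source = strategy, ...) {
  strategy <- match.arg(strategy)
  label_set <- cohort_label_set(cohort)
  texts <- case_record_text(cohort)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    if (strategy == "comprehensive") {
      r <- run_comprehensive(cohort$case_id[i], texts[i], predictor,
                             label_set, ...)
      n_failed <- as.integer(r$parse_failed)
      failed <- r$parse_failed
    } else {
      r <- run_targeted(cohort$case_id[i], texts[i], predictor,
                        label_set, ...)
      n_failed <- sum(r$verdicts$parse_failed)
      failed <- n_failed > 0
    }
    d <- r$diagnoses
    attr(d, "sentinel") <- NULL
    list(diagnoses = d, failed = failed, n_failed = as.integer(n_failed),
         n_calls = as.integer(r$n_calls), sentinel = r$sentinel)
  })
  list(
    predictions = tibble::tibble(
      case_id = cohort$case_id, source = source, run = as.integer(run),
      diagnoses = lapply(rows, `[[`, "diagnoses")
    ),
    manifest = tibble::tibble(
      case_id = cohort$case_id, strategy = strategy, run = as.integer(run),
      parse_failed = vapply(rows, `[[`, logical(1), "failed"),
      n_failed_units = vapply(rows, `[[`, integer(1), "n_failed"),
      n_calls = vapply(rows, `[[`, integer(1), "n_calls"),
      sentinel = vapply(rows, `[[`, logical(1), "sentinel")
    )
  )
}
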