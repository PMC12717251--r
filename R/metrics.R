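#' Set-based micro- and macro-averaged evaluation metrics
#'
#' Each case is a pair of diagnosis sets: the gold standard Y and the
#' prediction Y-hat. Per-case counts are pure set arithmetic
#' (TP = |Y intersect Y-hat|, FP = |Y-hat minus Y|, FN = |Y minus Y-hat|).
#' Micro averaging pools the counts globally before computing
#' precision/recall/F1; macro averaging computes per-case metrics with
#' per-case zero-denominator rules and averages them over cases. In lenient
#' mode set elements are labels; in strict mode they are (label, grade)
#' pairs, so a correct label with the wrong severity counts as both a false
#' positive and a false negative.
#'
#' @name metrics
NULL

#' Normalize a diagnosis list into a set
#'
#' Dedupes diagnoses, projects to labels in lenient mode, and keys on
#' (label, grade) pairs in strict mode. Conflicting duplicate grades for one
#' label in strict mode keep the most severe grade and set attribute
#' `grade_conflict`. The sentinel never appears here: an empty input is the
#' empty set.
#'
#' @param diagnoses diagnosis tibble (`label`, `grade`).
#' @param strict key on (label, grade) rather than label alone.
#' @return tibble with columns `label`, `grade` (lenient mode collapses
#'   `grade` to "unspecified") and a unique `key` column used for set
#'   arithmetic; attribute `grade_conflict` flags severity conflicts.
#' @export
normalize_diagnoses <- function(diagnoses, strict = FALSE) {
  lab <- canonical_label(diagnoses$label)
  grade <- diagnoses$grade
  conflict <- FALSE
  if (strict) {
    # one grade per label: conflicts resolved toward greater severity
    if (length(lab) > 0) {
      ord <- order(lab, -.grade_rank(grade))
      lab <- lab[ord]; grade <- grade[ord]
      dup_label <- duplicated(lab)
      conflict <- any(dup_label &
                        grade[match(lab, lab)] != grade)
      keep <- !dup_label
      lab <- lab[keep]; grade <- grade[keep]
    }
    key <- paste(lab, grade, sep = "|")
  } else {
    keep <- !duplicated(lab)
    lab <- lab[keep]
    grade <- rep("unspecified", length(lab))
    key <- lab
  }
  out <- tibble::tibble(label = lab, grade = grade, key = key)
  attr(out, "grade_conflict") <- isTRUE(conflict)
  if (isTRUE(conflict)) {
    warning("conflicting duplicate grades; kept the more severe grade",
            call. = FALSE)
  }
  out
}

#' Per-case true/false positive and false negative counts
#'
#' @param gold,pred diagnosis tibbles for the same case.
#' @param strict match on (label, grade) pairs rather than labels.
#' @return one-row tibble with `tp`, `fp`, `fn`.
#' @examples
#' case_counts(diagnosis_set(c("a", "b")), diagnosis_set(c("b", "c")))
#' @export
case_counts <- function(gold, pred, strict = FALSE) {
  g <- suppressWarnings(normalize_diagnoses(gold, strict = strict))
  p <- suppressWarnings(normalize_diagnoses(pred, strict = strict))
  tp <- length(intersect(g$key, p$key))
  tibble::tibble(tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp)
}

# set keys for one diagnosis tibble, deduped; strict keeps the most severe
# grade per label (same semantics as normalize_diagnoses, minus the warning)
.diag_keys <- function(d, strict) {
  lab <- canonical_label(d$label)
  if (!strict) return(unique(lab))
  if (anyDuplicated(lab)) {
    ord <- order(lab, -.grade_rank(d$grade))
    lab2 <- lab[ord]; gr <- d$grade[ord]
    keep <- !duplicated(lab2)
    paste(lab2[keep], gr[keep], sep = "|")
  } else {
    paste(lab, d$grade, sep = "|")
  }
}

# counts table for one (gold, prediction) run, one row per case
.counts_for_run <- function(gold_list, pred_list, strict = FALSE) {
  n <- length(gold_list)
  tp <- fp <- fn <- integer(n)
  for (i in seq_len(n)) {
    gk <- .diag_keys(gold_list[[i]], strict)
    pk <- .diag_keys(pred_list[[i]], strict)
    t <- length(intersect(gk, pk))
    tp[i] <- t; fp[i] <- length(pk) - t; fn[i] <- length(gk) - t
  }
  tibble::tibble(tp = tp, fp = fp, fn = fn)
}

.prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, f1 = f1)
}

#' Micro-averaged precision, recall and F1
#'
#' Pools TP/FP/FN over all cases, then applies the global zero-denominator
#' rules (a zero denominator yields 0.0 for that metric).
#'
#' @param counts tibble with columns `tp`, `fp`, `fn`, one row per case.
#' @param strict flag recorded in the result.
#' @return one-row tibble: `mode`, `strict`, `n_cases`, `precision`,
#'   `recall`, `f1`, and the pooled `tp`, `fp`, `fn`.
#' @export
micro_metrics <- function(counts, strict = FALSE) {
  if (nrow(counts) == 0) stop("no cases to evaluate", call. = FALSE)
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  m <- .prf(tp, fp, fn)
  tibble::tibble(mode = "micro", strict = strict, n_cases = nrow(counts),
                 precision = m[["precision"]], recall = m[["recall"]],
                 f1 = m[["f1"]], tp = tp, fp = fp, fn = fn)
}

#' Macro-averaged precision, recall and F1
#'
#' Computes per-case precision/recall/F1 with the per-case zero-denominator
#' rules, then takes the unweighted mean over cases. Note the printed edge
#' rules score a case with empty gold and empty prediction as F1 = 0; set
#' `empty_empty = "one"` to score such trivially correct cases as 1.0 in a
#' sensitivity analysis (the default is the rule as printed).
#'
#' @param counts tibble with columns `tp`, `fp`, `fn`, one row per case.
#' @param strict flag recorded in the result.
#' @param empty_empty `"zero"` (default) or `"one"`: per-case score when both
#'   gold and prediction are empty.
#' @return one-row tibble: `mode`, `strict`, `n_cases`, `precision`,
#'   `recall`, `f1` (pooled counts are reported as `NA`: macro has no global
#'   pooling).
#' @export
macro_metrics <- function(counts, strict = FALSE,
                          empty_empty = c("zero", "one")) {
  if (nrow(counts) == 0) stop("no cases to evaluate", call. = FALSE)
  empty_empty <- match.arg(empty_empty)
  per_case <- t(mapply(.prf, counts$tp, counts$fp, counts$fn))
  if (empty_empty == "one") {
    both_empty <- counts$tp + counts$fp == 0 & counts$tp + counts$fn == 0
    per_case[both_empty, ] <- 1
  }
  tibble::tibble(mode = "macro", strict = strict, n_cases = nrow(counts),
                 precision = mean(per_case[, "precision"]),
                 recall = mean(per_case[, "recall"]),
                 f1 = mean(per_case[, "f1"]),
                 tp = NA_integer_, fp = NA_integer_, fn = NA_integer_)
}

# align predictions to the gold cohort; errors list unmatched case ids
.align_predictions <- function(cohort, predictions) {
  missing <- setdiff(cohort$case_id, predictions$case_id)
  extra <- setdiff(predictions$case_id, cohort$case_id)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("prediction/gold case mismatch; missing: ",
         paste(utils::head(missing, 5), collapse = ", "),
         "; unmatched: ", paste(utils::head(extra, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(predictions[, c("case_id", "source", "run")])) {
    stop("duplicate (case_id, source, run) rows in predictions",
         call. = FALSE)
  }
  predictions
}

#' Evaluate prediction runs against a gold cohort
#'
#' Applies the metric definitions to every (source, run) in a predictions
#' table, in the requested micro/macro modes and lenient/strict settings.
#'
#' @param cohort gold-standard cohort tibble (with `truth` list-column).
#' @param predictions tibble with `case_id`, `source`, `run`, `diagnoses`;
#'   every gold case must appear in every run.
#' @param modes subset of `c("micro", "macro")`.
#' @param strict logical vector, e.g. `c(FALSE, TRUE)` for both settings.
#' @param empty_empty macro empty-case rule, see [macro_metrics()].
#' @return tibble with one row per source x run x mode x strict combination.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 8, seed = 1))
#' preds <- generate_predictions(cohort, predictor_profile(style = "ai_like"),
#'                               n_runs = 2, seed = 2)
#' evaluate_predictions(cohort, preds)
#' @export
evaluate_predictions <- function(cohort, predictions,
                                 modes = c("micro", "macro"),
                                 strict = FALSE,
                                 empty_empty = "zero") {
  modes <- match.arg(modes, several.ok = TRUE)
  out <- list()
  for (src in unique(predictions$source)) {
    psrc <- predictions[predictions$source == src, , drop = FALSE]
    .align_predictions(cohort, psrc)
    for (r in sort(unique(psrc$run))) {
      prun <- psrc[psrc$run == r, , drop = FALSE]
      pred_list <- prun$diagnoses[match(cohort$case_id, prun$case_id)]
      for (st in strict) {
        counts <- .counts_for_run(cohort$truth, pred_list, strict = st)
        for (md in modes) {
          row <- if (md == "micro") {
            micro_metrics(counts, strict = st)
          } else {
            macro_metrics(counts, strict = st, empty_empty = empty_empty)
          }
          out[[length(out) + 1]] <-
            dplyr::mutate(row, source = src, run = r, .before = 1)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
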