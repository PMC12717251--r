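#' Stratified sensitivity analyses
#'
#' Three stratification schemes over a cohort: document-length quartiles of
#' the prompt token counts, complication-count strata of the gold standard,
#' and a documentation-quality median split of the PDQI-9 scores. Each
#' scheme partitions the case set (disjoint, exhaustive) and metrics are
#' recomputed within each stratum.
#'
#' @name stratification
NULL

#' Token-count quartile strata
#'
#' Assigns cases to quartiles Q1-Q4 of the empirical token-count
#' distribution. Ties are broken by stable case order so the four strata are
#' always as balanced as integer division allows; with fully tied counts the
#' split is degenerate (order-only) and a warning is raised.
#'
#' @param cases tibble with `case_id` and `token_count`.
#' @return tibble `case_id`, `scheme`, `stratum`, `stratum_mean_tokens`.
#' @export
token_quartiles <- function(cases) {
  n <- nrow(cases)
  if (n < 4) stop("need at least 4 cases for quartiles", call. = FALSE)
  if (length(unique(cases$token_count)) == 1) {
    warning("all token counts equal: quartile split is order-only",
            call. = FALSE)
  }
  rank_stable <- order(order(cases$token_count))  # ties keep input order
  stratum <- paste0("Q", ceiling(rank_stable * 4 / n))
  means <- tapply(cases$token_count, stratum, mean)
  tibble::tibble(case_id = cases$case_id, scheme = "token_quartile",
                 stratum = stratum,
                 stratum_mean_tokens = as.numeric(means[stratum]))
}

#' Complication-count strata
#'
#' Strata by the size of each case's gold diagnosis set. The default scheme
#' uses levels `<=1`, `2`, `>=3`; the alternative preset `"0_1_ge2"`
#' (levels `0`, `1`, `>=2`) reflects a second grouping described for the
#' same analysis, exposed as configuration because the two descriptions are
#' inconsistent in the source material of this design.
#'
#' @param gold tibble with `case_id` and a diagnosis list-column (`truth` or
#'   `diagnoses`).
#' @param scheme `"le1_2_ge3"` (default) or `"0_1_ge2"`.
#' @return tibble `case_id`, `scheme`, `stratum`, `n_complications`.
#' @export
complication_strata <- function(gold, scheme = c("le1_2_ge3", "0_1_ge2")) {
  scheme <- match.arg(scheme)
  col <- if ("truth" %in% names(gold)) "truth" else "diagnoses"
  sizes <- vapply(gold[[col]], nrow, integer(1))
  stratum <- if (scheme == "le1_2_ge3") {
    ifelse(sizes <= 1, "<=1", ifelse(sizes == 2, "2", ">=3"))
  } else {
    ifelse(sizes == 0, "0", ifelse(sizes == 1, "1", ">=2"))
  }
  tibble::tibble(case_id = gold$case_id, scheme = "complication_count",
                 stratum = stratum, n_complications = sizes)
}

#' Documentation-quality median split
#'
#' High-quality iff the PDQI-9 score exceeds the cohort median; scores at or
#' below the median (including exact ties) are assigned to the low-quality
#' group, which keeps the split deterministic. All-equal scores collapse to
#' a single low group with a warning.
#'
#' @param cases tibble with `case_id` and `pdqi_score`.
#' @return tibble `case_id`, `scheme`, `stratum`, `median_pdqi`.
#' @export
quality_strata <- function(cases) {
  if (!"pdqi_score" %in% names(cases) || all(is.na(cases$pdqi_score))) {
    stop("cases carry no pdqi_score: quality stratification needs PDQI-9 scores",
         call. = FALSE)
  }
  med <- stats::median(cases$pdqi_score)
  if (length(unique(cases$pdqi_score)) == 1) {
    warning("all PDQI-9 scores equal: every case assigned to 'low'",
            call. = FALSE)
  }
  tibble::tibble(case_id = cases$case_id, scheme = "pdqi_quality",
                 stratum = ifelse(cases$pdqi_score > med, "high", "low"),
                 median_pdqi = med)
}

#' Metrics within strata
#'
#' Applies the metric definitions within each stratum of an assignment
#' table. Because micro counts pool additively, the per-stratum pooled
#' TP/FP/FN always sum to the whole-cohort counts. An empty stratum yields a
#' flagged row with `n_cases = 0` and `NA` metrics.
#'
#' @param assignments tibble from one of the stratification functions; must
#'   cover every evaluated case.
#' @param cohort gold-standard cohort tibble.
#' @param predictions prediction tibble (`case_id`, `source`, `run`,
#'   `diagnoses`).
#' @param modes,strict,empty_empty passed to [evaluate_predictions()].
#' @return tibble with one row per stratum x source x run x mode x strict,
#'   plus `scheme`, `stratum` and per-stratum `n_cases`.
#' @export
stratified_metrics <- function(assignments, cohort, predictions,
                               modes = "micro", strict = FALSE,
                               empty_empty = "zero") {
  uncovered <- setdiff(cohort$case_id, assignments$case_id)
  if (length(uncovered) > 0) {
    stop("assignments do not cover cases: ",
         paste(utils::head(uncovered, 5), collapse = ", "), call. = FALSE)
  }
  strata <- unique(assignments$stratum)
  out <- lapply(strata, function(s) {
    ids <- assignments$case_id[assignments$stratum == s]
    sub_cohort <- cohort[cohort$case_id %in% ids, , drop = FALSE]
    attr(sub_cohort, "label_set") <- attr(cohort, "label_set")
    sub_pred <- predictions[predictions$case_id %in% ids, , drop = FALSE]
    if (nrow(sub_cohort) == 0) {
      return(tibble::tibble(scheme = assignments$scheme[1], stratum = s,
                            source = NA_character_, run = NA_integer_,
                            mode = NA_character_, strict = NA,
                            n_cases = 0L, precision = NA_real_,
                            recall = NA_real_, f1 = NA_real_, empty = TRUE))
    }
    res <- evaluate_predictions(sub_cohort, sub_pred, modes = modes,
                                strict = strict, empty_empty = empty_empty)
    dplyr::mutate(res, scheme = assignments$scheme[1], stratum = s,
                  empty = FALSE, .before = 1)
  })
  dplyr::bind_rows(out)
}
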