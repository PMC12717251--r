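#' Statistical comparison, agreement and consensus procedures
#'
#' Patient-level bootstrap paired testing across repeated inference runs,
#' t-distribution intervals across runs for figures, Bonferroni correction,
#' Fleiss' kappa over pooled (case, label) items, and majority-consensus gold
#' standards.
#'
#' @name comparison-stats
NULL

#' Bootstrap test configuration
#'
#' @param iterations bootstrap iterations B (default 2000).
#' @param side test side; the default `"greater"` tests whether strategy B
#'   improves on strategy A.
#' @param alpha significance level, in (0, 1).
#' @param m Bonferroni family size (default 2: the two sequential strategy
#'   comparisons that form one family).
#' @param seed integer seed; results are deterministic given the seed.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(iterations = 2000,
                             side = c("greater", "less", "two_sided"),
                             alpha = 0.05, m = 2, seed = 1L) {
  side <- match.arg(side)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (m < 1) stop("family size m must be >= 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations), side = side,
                 alpha = alpha, m = as.integer(m), seed = seed),
            class = "bootstrap_config")
}

#' Bonferroni correction
#'
#' @param p raw p-value(s) in \[0, 1\].
#' @param m family size (number of comparisons).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @examples
#' bonferroni(0.0055, 2)  # 0.011
#' bonferroni(0.602, 2)   # capped at 1
#' @export
bonferroni <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, m * p)
}

#' t-distribution interval across repeated runs
#'
#' Parametric interval `mean +/- t_{(1+level)/2, R-1} * sd / sqrt(R)` used
#' for visual presentation of per-run metric spread.
#'
#' @param values numeric vector of per-run metric values (length >= 2).
#' @param level confidence level (default 0.95).
#' @return one-row tibble with `mean`, `lo`, `hi`, `n_runs`.
#' @export
t_interval <- function(values, level = 0.95) {
  R <- length(values)
  if (R < 2) stop("need at least 2 values for a t interval", call. = FALSE)
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, df = R - 1) * stats::sd(values) / sqrt(R)
  tibble::tibble(mean = m, lo = m - half, hi = m + half, n_runs = R)
}

# per-case, per-run statistic tables for fast bootstrap evaluation:
# micro needs tp/fp/fn; macro needs the per-case metric value
.boot_stat_tables <- function(cohort, predictions, mode, strict) {
  runs <- sort(unique(predictions$run))
  n <- nrow(cohort)
  tabs <- lapply(runs, function(r) {
    prun <- predictions[predictions$run == r, , drop = FALSE]
    pred_list <- prun$diagnoses[match(cohort$case_id, prun$case_id)]
    if (anyNA(match(cohort$case_id, prun$case_id))) {
      stop("run ", r, " does not cover every gold case", call. = FALSE)
    }
    .counts_for_run(cohort$truth, pred_list, strict = strict)
  })
  list(
    runs = runs,
    tp = vapply(tabs, function(x) x$tp, numeric(n)),
    fp = vapply(tabs, function(x) x$fp, numeric(n)),
    fn = vapply(tabs, function(x) x$fn, numeric(n)),
    per_case = if (mode == "macro") {
      lapply(tabs, function(x) t(mapply(.prf, x$tp, x$fp, x$fn)))
    } else NULL
  )
}

.boot_metric <- function(tab, idx, run_col, metric, mode) {
  if (mode == "micro") {
    m <- .prf(sum(tab$tp[idx, run_col]), sum(tab$fp[idx, run_col]),
              sum(tab$fn[idx, run_col]))
    m[[metric]]
  } else {
    mean(tab$per_case[[run_col]][idx, metric])
  }
}

#' Patient-level bootstrap paired test
#'
#' Compares two strategies' metric (B minus A) by resampling patients with
#' replacement and, in each of B iterations, drawing one random inference
#' run per strategy to carry both patient-level and inference-level
#' variability. Micro metrics are recomputed on each resample by pooling the
#' resampled cases' counts. Reports the mean bootstrap difference, the
#' percentile 95% interval, the single-sided p-value (for `side =
#' "greater"`, the proportion of bootstrap differences <= 0, a plain
#' proportion so p is always a multiple of 1/B) and its Bonferroni-corrected
#' value.
#'
#' @param cohort gold-standard cohort tibble.
#' @param runs_a,runs_b prediction tibbles (`case_id`, `run`, `diagnoses`)
#'   for strategies A and B, covering the same cases with >= 1 runs each.
#' @param metric one of `"f1"`, `"precision"`, `"recall"`.
#' @param mode `"micro"` or `"macro"`.
#' @param strict strict (label + severity) matching.
#' @param config a [bootstrap_config()].
#' @return object of class `boot_compare`; see [tidy.boot_compare()].
#' @export
bootstrap_paired_test <- function(cohort, runs_a, runs_b,
                                  metric = c("f1", "precision", "recall"),
                                  mode = c("micro", "macro"), strict = FALSE,
                                  config = bootstrap_config()) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  stopifnot(inherits(config, "bootstrap_config"))
  if (!setequal(runs_a$case_id, cohort$case_id) ||
      !setequal(runs_b$case_id, cohort$case_id)) {
    stop("both strategies must cover exactly the gold cases", call. = FALSE)
  }
  low_B <- config$iterations < 100
  if (low_B) {
    warning("fewer than 100 bootstrap iterations: CI unreliable",
            call. = FALSE)
  }
  tab_a <- .boot_stat_tables(cohort, runs_a, mode, strict)
  tab_b <- .boot_stat_tables(cohort, runs_b, mode, strict)
  n <- nrow(cohort)
  B <- config$iterations

  diffs <- .with_seed(config$seed, {
    idx_mat <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    ra <- sample.int(length(tab_a$runs), B, replace = TRUE)
    rb <- sample.int(length(tab_b$runs), B, replace = TRUE)
    vapply(seq_len(B), function(b) {
      idx <- idx_mat[, b]
      .boot_metric(tab_b, idx, rb[b], metric, mode) -
        .boot_metric(tab_a, idx, ra[b], metric, mode)
    }, numeric(1))
  })

  p <- switch(config$side,
              greater = mean(diffs <= 0),
              less = mean(diffs >= 0),
              two_sided = min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0))))
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975), type = 7))
  structure(
    list(mean_diff = mean(diffs), ci_low = ci[1], ci_high = ci[2],
         p = p, p_corrected = bonferroni(p, config$m), B = B,
         side = config$side, metric = metric, mode = mode, strict = strict,
         m = config$m, n_cases = n, alpha = config$alpha,
         low_B = low_B, diffs = diffs),
    class = "boot_compare"
  )
}

#' @export
print.boot_compare <- function(x, ...) {
  cat("Patient-level bootstrap paired test (", x$B, " iterations, side = ",
      x$side, ")\n", sep = "")
  cat(sprintf("  %s %s%s: mean diff %.4f, 95%% CI [%.4f, %.4f]\n",
              x$mode, x$metric, if (x$strict) " (strict)" else "",
              x$mean_diff, x$ci_low, x$ci_high))
  cat(sprintf("  p = %.4g, Bonferroni-corrected (m = %d) p = %.4g\n",
              x$p, x$m, x$p_corrected))
  invisible(x)
}

#' Tidy a bootstrap comparison
#'
#' @param x a `boot_compare` object.
#' @param ... unused.
#' @return one-row tibble with the comparison's estimates, matching the
#'   columns of the comparison report (mean difference, 95% CI bounds,
#'   raw and corrected p-values).
#' @method tidy boot_compare
#' @export
tidy.boot_compare <- function(x, ...) {
  tibble::tibble(metric = x$metric, mode = x$mode, strict = x$strict,
                 mean_diff = x$mean_diff, ci_low = x$ci_low,
                 ci_high = x$ci_high, p = x$p, p_corrected = x$p_corrected)
}

#' Glance at a bootstrap comparison
#'
#' @param x a `boot_compare` object.
#' @param ... unused.
#' @return one-row tibble of test-level summaries (iterations, side, family
#'   size, case count, significance at alpha after correction).
#' @method glance boot_compare
#' @export
glance.boot_compare <- function(x, ...) {
  tibble::tibble(B = x$B, side = x$side, m = x$m, n_cases = x$n_cases,
                 alpha = x$alpha,
                 significant = x$p_corrected < x$alpha)
}

# raters must all cover the same case set
.check_shared_cases <- function(annotations) {
  by_rater <- split(annotations$case_id, annotations$rater)
  if (length(by_rater) < 2) {
    stop("need at least 2 raters", call. = FALSE)
  }
  ref <- sort(by_rater[[1]])
  for (r in names(by_rater)) {
    if (!identical(sort(by_rater[[r]]), ref)) {
      stop("raters cover different case sets (", r, " differs)",
           call. = FALSE)
    }
  }
  invisible(ref)
}

# case x label x rater presence array
.annotation_array <- function(annotations, label_set) {
  cases <- sort(unique(annotations$case_id))
  raters <- sort(unique(annotations$rater))
  labels <- canonical_label(label_set$label)
  arr <- array(FALSE, dim = c(length(cases), length(labels), length(raters)),
               dimnames = list(cases, labels, raters))
  for (i in seq_len(nrow(annotations))) {
    d <- annotations$diagnoses[[i]]
    j <- match(canonical_label(d$label), labels)
    j <- j[!is.na(j)]
    arr[annotations$case_id[i], j, annotations$rater[i]] <- TRUE
  }
  arr
}

.fleiss_from_counts <- function(n_present, n_raters) {
  # n_present: count of raters marking each pooled (case, label) item present
  N <- length(n_present)
  n <- n_raters
  p_present <- sum(n_present) / (N * n)
  p_absent <- 1 - p_present
  P_i <- (n_present^2 + (n - n_present)^2 - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  P_e <- p_present^2 + p_absent^2
  if (1 - P_e < 1e-12) {
    return(if (P_bar >= 1 - 1e-12) 1 else NA_real_)
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Fleiss' kappa over pooled case-label items
#'
#' Treats every (case, label) pair as one item rated present/absent by all
#' raters and computes Fleiss' kappa over all items pooled (all complication
#' categories combined). The confidence interval is a case-level bootstrap
#' percentile interval: cases are resampled with replacement and kappa
#' recomputed over their pooled items.
#'
#' @param annotations tibble with columns `rater`, `case_id`, `diagnoses`
#'   (list-column); every rater must cover the identical case set.
#' @param label_set label set tibble defining the pooled items.
#' @param ci compute the bootstrap interval.
#' @param B bootstrap resamples for the interval (default 2000).
#' @param level interval level.
#' @param seed integer seed for the bootstrap.
#' @return object of class `fleiss_kappa` with elements `kappa`, `ci_low`,
#'   `ci_high`, `n_cases`, `n_raters`, `n_items`.
#' @export
fleiss_kappa <- function(annotations, label_set = default_label_set(),
                         ci = TRUE, B = 2000, level = 0.95, seed = 1L) {
  .check_shared_cases(annotations)
  arr <- .annotation_array(annotations, label_set)
  n_raters <- dim(arr)[3]
  # per (case, label): number of raters marking present
  counts <- apply(arr, c(1, 2), sum)
  kappa <- .fleiss_from_counts(as.vector(counts), n_raters)
  ci_low <- ci_high <- NA_real_
  if (ci) {
    n_cases <- nrow(counts)
    ks <- .with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- sample.int(n_cases, n_cases, replace = TRUE)
        .fleiss_from_counts(as.vector(counts[idx, , drop = FALSE]), n_raters)
      }, numeric(1))
    })
    qs <- stats::quantile(ks, c((1 - level) / 2, (1 + level) / 2),
                          na.rm = TRUE, type = 7)
    ci_low <- unname(qs[1]); ci_high <- unname(qs[2])
  }
  structure(
    list(kappa = kappa, ci_low = ci_low, ci_high = ci_high,
         n_cases = nrow(counts), n_raters = n_raters,
         n_items = length(counts), level = level),
    class = "fleiss_kappa"
  )
}

#' @export
print.fleiss_kappa <- function(x, ...) {
  cat(sprintf("Fleiss' kappa = %.3f", x$kappa))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (%.0f%% CI %.3f-%.3f)", 100 * x$level, x$ci_low, x$ci_high))
  }
  cat(sprintf("\n  %d cases x %d raters, %d pooled items\n",
              x$n_cases, x$n_raters, x$n_items))
  invisible(x)
}

#' Tidy a Fleiss' kappa result
#'
#' @param x a `fleiss_kappa` object.
#' @param ... unused.
#' @return one-row tibble with `kappa`, `ci_low`, `ci_high`.
#' @method tidy fleiss_kappa
#' @export
tidy.fleiss_kappa <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Glance at a Fleiss' kappa result
#'
#' @param x a `fleiss_kappa` object.
#' @param ... unused.
#' @return one-row tibble with the item and rater counts.
#' @method glance fleiss_kappa
#' @export
glance.fleiss_kappa <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, n_raters = x$n_raters,
                 n_items = x$n_items, level = x$level)
}

#' Majority-consensus gold standard
#'
#' A diagnosis enters the per-case gold standard iff at least `threshold`
#' raters include its label; its grade is the majority grade among the
#' including raters, with ties broken toward the more severe grade and
#' flagged for audit.
#'
#' @param annotations tibble with columns `rater`, `case_id`, `diagnoses`.
#' @param threshold minimum number of endorsing raters (default 2, the
#'   majority of a three-physician panel).
#' @param label_set label set tibble.
#' @return tibble with `case_id`, `diagnoses` (list-column) and
#'   `grade_tie_labels` (list-column of labels whose grade was tie-broken).
#' @export
consensus_gold <- function(annotations, threshold = 2,
                           label_set = default_label_set()) {
  .check_shared_cases(annotations)
  n_raters <- length(unique(annotations$rater))
  if (n_raters < threshold) {
    stop("threshold (", threshold, ") exceeds the number of raters (",
         n_raters, ")", call. = FALSE)
  }
  cases <- sort(unique(annotations$case_id))
  canon <- canonical_label(label_set$label)
  rows <- lapply(cases, function(cid) {
    sets <- annotations$diagnoses[annotations$case_id == cid]
    votes <- dplyr::bind_rows(lapply(sets, function(d) {
      d <- suppressWarnings(normalize_diagnoses(d, strict = TRUE))
      tibble::tibble(label = d$label, grade = d$grade)
    }))
    if (nrow(votes) == 0) {
      return(list(case_id = cid, diagnoses = diagnosis_set(),
                  ties = character()))
    }
    by_label <- split(votes$grade, votes$label)
    keep <- names(by_label)[lengths(by_label) >= threshold]
    ties <- character()
    grades <- vapply(keep, function(lb) {
      tab <- table(by_label[[lb]])
      top <- names(tab)[tab == max(tab)]
      if (length(top) > 1) {
        ties <<- c(ties, lb)
        top <- top[which.max(.grade_rank(top))]
      }
      top
    }, character(1))
    # restore canonical display names from the label set where known
    disp <- label_set$label[match(keep, canon)]
    disp[is.na(disp)] <- keep[is.na(disp)]
    list(case_id = cid, diagnoses = diagnosis_set(disp, unname(grades)),
         ties = ties)
  })
  tibble::tibble(
    case_id = vapply(rows, `[[`, character(1), "case_id"),
    diagnoses = lapply(rows, `[[`, "diagnoses"),
    grade_tie_labels = lapply(rows, `[[`, "ties")
  )
}
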