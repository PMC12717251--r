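#' Synthetic dual-center cohort generation
#'
#' Generators for cohorts, repeated-run predictor outputs and rater
#' annotations with the statistical structure the downstream evaluation
#' assumes: per-center label prevalences, severity grades, right-skewed
#' document token counts, documentation-quality scores, and stochastic
#' predictors with controllable sensitivity / false-positive profiles.
#'
#' @name synthetic-cohort
NULL

# run code under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Specify a synthetic cohort
#'
#' Defaults emulate a dual-center surgical cohort: per-center complication
#' prevalences taken from the observed two-center case counts, log-normal
#' document token counts with center means 6841.6 and 8084.3 (center 1 more
#' concentrated, center 2 broader), and documentation-quality (PDQI-9) scores
#' on the 1-5 scale.
#'
#' @param n_patients number of cases to generate.
#' @param center_mix named numeric, proportion of cases per center; must sum
#'   to 1. Default is the observed 146:102 split.
#' @param label_set tibble with columns `label`, `graded`
#'   (see [default_label_set()]).
#' @param label_prevalence tibble with columns `label`, `center1`, `center2`,
#'   per-center probabilities in \[0,1\]. Default: observed prevalences, zero
#'   for the placeholder labels.
#' @param severity_dist tibble with columns `label`, `mild`, `moderate`,
#'   `severe`; each row sums to 1. Ignored for ungraded labels, whose grade is
#'   always "unspecified". Default 0.5/0.3/0.2 for every graded label.
#' @param token_count_dist list with per-center elements `center1`, `center2`,
#'   each `list(meanlog=, sdlog=)` for a log-normal token count.
#' @param pdqi_dist list `list(mean=, sd=)`; scores are drawn normal and
#'   clipped to \[1, 5\].
#' @param enforce_infection_exclusivity keep truth sets clinically coherent:
#'   when any specific infectious complication is present, "infection of
#'   unknown source" is excluded from the same case's truth, mirroring the
#'   redundancy rule a consensus panel applies to the gold standard. Set
#'   `FALSE` for fully independent label sampling.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_patients = 50, seed = 1)
#' @export
cohort_spec <- function(n_patients = 248,
                        center_mix = c(center1 = 146 / 248, center2 = 102 / 248),
                        label_set = default_label_set(),
                        label_prevalence = default_label_prevalence(label_set),
                        severity_dist = default_severity_dist(label_set),
                        token_count_dist = default_token_count_dist(),
                        pdqi_dist = list(mean = 3.8, sd = 0.5),
                        enforce_infection_exclusivity = TRUE,
                        seed = 1L) {
  spec <- structure(
    list(n_patients = n_patients, center_mix = center_mix,
         label_set = label_set, label_prevalence = label_prevalence,
         severity_dist = severity_dist, token_count_dist = token_count_dist,
         pdqi_dist = pdqi_dist,
         enforce_infection_exclusivity = isTRUE(enforce_infection_exclusivity),
         seed = seed),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_patients, " patients, ",
      nrow(x$label_set), " labels, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Validate a cohort specification
#'
#' Checks probabilities, severity rows and sizes; errors name the offending
#' field so misconfiguration is diagnosable.
#'
#' @param spec a `cohort_spec`.
#' @return the spec, or an error naming the invalid field.
#' @export
validate_cohort_spec <- function(spec) {
  stop_field <- function(field, msg) {
    stop("invalid cohort spec field '", field, "': ", msg, call. = FALSE)
  }
  if (!is.numeric(spec$n_patients) || length(spec$n_patients) != 1 ||
      is.na(spec$n_patients) || spec$n_patients < 1) {
    stop_field("n_patients", "must be a single count >= 1")
  }
  if (length(spec$center_mix) != 2 || any(spec$center_mix < 0) ||
      abs(sum(spec$center_mix) - 1) > 1e-9) {
    stop_field("center_mix", "two non-negative proportions summing to 1")
  }
  validate_label_set(spec$label_set)
  lp <- spec$label_prevalence
  if (!all(c("label", "center1", "center2") %in% names(lp))) {
    stop_field("label_prevalence", "needs columns label, center1, center2")
  }
  if (!setequal(lp$label, spec$label_set$label)) {
    stop_field("label_prevalence", "labels must match the label set")
  }
  probs <- c(lp$center1, lp$center2)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop_field("label_prevalence", "probabilities must lie in [0, 1]")
  }
  sd <- spec$severity_dist
  if (!all(c("label", "mild", "moderate", "severe") %in% names(sd))) {
    stop_field("severity_dist", "needs columns label, mild, moderate, severe")
  }
  graded <- spec$label_set$label[spec$label_set$graded]
  if (!all(graded %in% sd$label)) {
    stop_field("severity_dist", "missing rows for graded labels")
  }
  rows <- sd[sd$label %in% graded, c("mild", "moderate", "severe")]
  if (nrow(rows) > 0) {
    sums <- rowSums(as.matrix(rows))
    if (any(abs(sums - 1) > 1e-9) || any(as.matrix(rows) < 0)) {
      stop_field("severity_dist", "graded rows must be probabilities summing to 1")
    }
  }
  for (ctr in c("center1", "center2")) {
    tc <- spec$token_count_dist[[ctr]]
    if (is.null(tc$meanlog) || is.null(tc$sdlog) || tc$sdlog <= 0) {
      stop_field("token_count_dist", paste0(ctr, " needs meanlog and sdlog > 0"))
    }
  }
  if (is.null(spec$pdqi_dist$mean) || is.null(spec$pdqi_dist$sd) ||
      spec$pdqi_dist$sd <= 0) {
    stop_field("pdqi_dist", "needs mean and sd > 0")
  }
  spec
}

#' Default per-center complication prevalences
#'
#' Observed per-label case proportions in the two centers (counts over 146
#' and 102 cases respectively); labels outside the named 20 get prevalence 0.
#'
#' @param label_set label set tibble; prevalences are returned for exactly
#'   these labels.
#' @return tibble with columns `label`, `center1`, `center2`.
#' @export
default_label_prevalence <- function(label_set = default_label_set()) {
  counts1 <- c(
    "paralytic ileus" = 36, "organ/space surgical site infection" = 21,
    "infection of unknown source" = 22,
    "myocardial injury after non-cardiac surgery" = 20,
    "anastomotic leakage" = 15, "pneumonia" = 10,
    "postoperative bleeding" = 10, "acute kidney injury" = 7,
    "superficial surgical site infection" = 4, "arrhythmia" = 7,
    "cardiogenic pulmonary edema" = 7, "deep vein thrombosis" = 5,
    "deep surgical site infection" = 3, "gastrointestinal bleeding" = 4,
    "delirium" = 5, "acute respiratory distress syndrome" = 4,
    "pulmonary embolism" = 3, "myocardial infarction" = 2,
    "bloodstream infection" = 1, "stroke" = 0
  )
  counts2 <- c(
    "paralytic ileus" = 20, "organ/space surgical site infection" = 16,
    "infection of unknown source" = 3,
    "myocardial injury after non-cardiac surgery" = 7,
    "anastomotic leakage" = 10, "pneumonia" = 17,
    "postoperative bleeding" = 15, "acute kidney injury" = 12,
    "superficial surgical site infection" = 8, "arrhythmia" = 6,
    "cardiogenic pulmonary edema" = 1, "deep vein thrombosis" = 9,
    "deep surgical site infection" = 7, "gastrointestinal bleeding" = 6,
    "delirium" = 0, "acute respiratory distress syndrome" = 2,
    "pulmonary embolism" = 1, "myocardial infarction" = 1,
    "bloodstream infection" = 2, "stroke" = 1
  )
  p1 <- unname(counts1[label_set$label]) / 146
  p2 <- unname(counts2[label_set$label]) / 102
  tibble::tibble(
    label = label_set$label,
    center1 = ifelse(is.na(p1), 0, p1),
    center2 = ifelse(is.na(p2), 0, p2)
  )
}

#' Default severity distribution
#'
#' Mild/moderate/severe probabilities per graded label. The source tables
#' report only marginal label prevalences, so a common 0.5/0.3/0.2 split
#' (most complications mild, few severe) is used for every graded label.
#'
#' @param label_set label set tibble.
#' @return tibble with columns `label`, `mild`, `moderate`, `severe`.
#' @export
default_severity_dist <- function(label_set = default_label_set()) {
  tibble::tibble(label = label_set$label,
                 mild = 0.5, moderate = 0.3, severe = 0.2)
}

#' Default per-center token-count distributions
#'
#' Log-normal families whose means match the observed per-center prompt token
#' means (center 1: 6841.6, concentrated; center 2: 8084.3, broader spread).
#'
#' @param mean1,mean2 per-center mean token counts.
#' @param sdlog1,sdlog2 log-scale spread per center.
#' @return list with `center1` and `center2` elements `list(meanlog, sdlog)`.
#' @export
default_token_count_dist <- function(mean1 = 6841.6, mean2 = 8084.3,
                                     sdlog1 = 0.35, sdlog2 = 0.55) {
  list(
    center1 = list(meanlog = log(mean1) - sdlog1^2 / 2, sdlog = sdlog1),
    center2 = list(meanlog = log(mean2) - sdlog2^2 / 2, sdlog = sdlog2)
  )
}

#' Generate a synthetic cohort
#'
#' One row per case with its center, true diagnosis set (list-column of
#' `label`/`grade` tibbles), document token count and PDQI-9 quality score.
#' Deterministic given the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return tibble with columns `case_id`, `center`, `truth` (list-column),
#'   `token_count`, `pdqi_score`; the label set is attached as attribute
#'   `label_set`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 20, seed = 42))
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- as.integer(spec$n_patients)
  labels <- spec$label_set$label
  graded <- spec$label_set$graded
  L <- length(labels)

  .with_seed(spec$seed, {
    center <- sample(c("center1", "center2"), n, replace = TRUE,
                     prob = unname(spec$center_mix))

    lp <- spec$label_prevalence[match(labels, spec$label_prevalence$label), ]
    prev <- rbind(center1 = lp$center1, center2 = lp$center2)
    pmat <- prev[center, , drop = FALSE]                       # n x L
    present <- matrix(stats::runif(n * L), n, L) < pmat

    if (isTRUE(spec$enforce_infection_exclusivity)) {
      canon <- canonical_label(labels)
      j_unknown <- match(canonical_label("infection of unknown source"), canon)
      j_spec <- which(canon %in% canonical_label(default_specific_infections()))
      if (!is.na(j_unknown) && length(j_spec) > 0) {
        redundant <- rowSums(present[, j_spec, drop = FALSE]) > 0
        present[redundant, j_unknown] <- FALSE
      }
    }

    sd_rows <- spec$severity_dist[match(labels, spec$severity_dist$label), ]
    grade_mat <- matrix("unspecified", n, L)
    for (j in seq_len(L)) {
      idx <- which(present[, j])
      if (length(idx) > 0 && graded[j]) {
        grade_mat[idx, j] <- sample(
          SEVERITY_GRADES, length(idx), replace = TRUE,
          prob = c(sd_rows$mild[j], sd_rows$moderate[j], sd_rows$severe[j])
        )
      }
    }

    token_count <- integer(n)
    for (ctr in c("center1", "center2")) {
      idx <- which(center == ctr)
      tc <- spec$token_count_dist[[ctr]]
      if (length(idx) > 0) {
        token_count[idx] <- pmax(
          1L, as.integer(round(stats::rlnorm(length(idx), tc$meanlog, tc$sdlog)))
        )
      }
    }
    pdqi <- pmin(5, pmax(1, stats::rnorm(n, spec$pdqi_dist$mean,
                                         spec$pdqi_dist$sd)))

    truth <- lapply(seq_len(n), function(i) {
      j <- which(present[i, ])
      diagnosis_set(labels[j], grade_mat[i, j])
    })

    out <- tibble::tibble(
      case_id = sprintf("case_%04d", seq_len(n)),
      center = center,
      truth = truth,
      token_count = token_count,
      pdqi_score = pdqi
    )
    attr(out, "label_set") <- spec$label_set
    out
  })
}

# label set attached to a cohort, falling back to the default
cohort_label_set <- function(cohort) {
  ls <- attr(cohort, "label_set")
  if (is.null(ls)) default_label_set() else ls
}

#' Describe a stochastic predictor
#'
#' A predictor profile gives, per label, the probability of detecting a truly
#' present complication (`sensitivity`) and of asserting an absent one
#' (`fpr`); a probability that a detected label's severity grade is perturbed
#' (`severity_confusion`); and the probability that a per-label verdict is
#' re-randomized between repeated inference runs (`run_flip`, the simplest
#' mechanism reproducing run-to-run sampling noise while preserving the
#' marginal rates).
#'
#' The two style presets mirror the observed behavioural signatures under a
#' low-prevalence multi-label regime: `ai_like` (high sensitivity, non-trivial
#' false-positive rate) yields micro recall above micro precision, and
#' `human_like` (conservative: lower sensitivity, very low false-positive
#' rate) the converse.
#'
#' @param sensitivity scalar or per-label named vector in \[0,1\].
#' @param fpr scalar or per-label named vector in \[0,1\].
#' @param severity_confusion probability a detected label's grade is perturbed.
#' @param run_flip probability a per-label verdict is redrawn on each run.
#' @param style optional preset, `"ai_like"` or `"human_like"`; fills
#'   `sensitivity`/`fpr` when those are missing.
#' @return object of class `predictor_profile`.
#' @examples
#' predictor_profile(style = "ai_like")
#' predictor_profile(sensitivity = 0.8, fpr = 0.05)
#' @export
predictor_profile <- function(sensitivity = NULL, fpr = NULL,
                              severity_confusion = 0.1, run_flip = 0.05,
                              style = NULL) {
  if (!is.null(style)) {
    style <- match.arg(style, c("ai_like", "human_like"))
    if (is.null(sensitivity)) {
      sensitivity <- switch(style, ai_like = 0.85, human_like = 0.60)
    }
    if (is.null(fpr)) {
      fpr <- switch(style, ai_like = 0.08, human_like = 0.015)
    }
  }
  if (is.null(sensitivity) || is.null(fpr)) {
    stop("provide sensitivity and fpr, or a style preset", call. = FALSE)
  }
  check_prob <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0 | x > 1)) {
      stop("profile field '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  check_prob(sensitivity, "sensitivity"); check_prob(fpr, "fpr")
  check_prob(severity_confusion, "severity_confusion")
  check_prob(run_flip, "run_flip")
  structure(
    list(sensitivity = sensitivity, fpr = fpr,
         severity_confusion = severity_confusion, run_flip = run_flip,
         style = style),
    class = "predictor_profile"
  )
}

#' @export
print.predictor_profile <- function(x, ...) {
  cat("<predictor_profile>",
      if (!is.null(x$style)) paste0(" style=", x$style) else "",
      " sensitivity=", paste(round(mean(x$sensitivity), 3)),
      " fpr=", paste(round(mean(x$fpr), 3)),
      " severity_confusion=", x$severity_confusion,
      " run_flip=", x$run_flip, "\n", sep = "")
  invisible(x)
}

# expand a scalar-or-named-vector profile field over the label vector;
# errors if the profile names labels outside the cohort's label set
.expand_profile_field <- function(x, labels, nm) {
  if (length(x) == 1 && is.null(names(x))) {
    return(rep(unname(x), length(labels)))
  }
  if (is.null(names(x))) {
    stop("profile field '", nm,
         "' must be a scalar or a named per-label vector", call. = FALSE)
  }
  unknown <- setdiff(canonical_label(names(x)), canonical_label(labels))
  if (length(unknown) > 0) {
    stop("profile field '", nm, "' references labels absent from the ",
         "cohort label set: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_real_, length(labels))
  idx <- match(canonical_label(names(x)), canonical_label(labels))
  out[idx] <- unname(x)
  if (anyNA(out)) {
    stop("profile field '", nm, "' must cover every label when named",
         call. = FALSE)
  }
  out
}

#' Generate repeated-run predictions for a cohort
#'
#' For each case and run, each truly present label is predicted with
#' probability `sensitivity`, each absent label with probability `fpr`;
#' detected labels keep the true grade except with probability
#' `severity_confusion` (perturbed to a different grade); false-positive
#' grades are drawn from the cohort's severity distribution. Across runs each
#' per-label verdict is redrawn with probability `run_flip`, otherwise held at
#' its base draw, so marginal rates are identical in every run.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param profile a [predictor_profile()].
#' @param n_runs number of repeated inference runs (default 5).
#' @param seed integer seed.
#' @param source identifier stored in the `source` column.
#' @param severity_dist severity distribution used for false-positive grades;
#'   defaults to [default_severity_dist()] on the cohort's label set.
#' @return tibble with columns `case_id`, `source`, `run`, `diagnoses`
#'   (list-column of diagnosis tibbles), one row per case x run.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 10, seed = 1))
#' preds <- generate_predictions(cohort, predictor_profile(style = "ai_like"),
#'                               n_runs = 2, seed = 9)
#' @export
generate_predictions <- function(cohort, profile, n_runs = 5, seed = 1L,
                                 source = profile$style %||% "predictor",
                                 severity_dist = NULL) {
  stopifnot(inherits(profile, "predictor_profile"))
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  label_set <- cohort_label_set(cohort)
  labels <- label_set$label
  graded <- label_set$graded
  L <- length(labels)
  n <- nrow(cohort)
  if (is.null(severity_dist)) severity_dist <- default_severity_dist(label_set)
  sd_rows <- severity_dist[match(labels, severity_dist$label), ]

  sens <- .expand_profile_field(profile$sensitivity, labels, "sensitivity")
  fpr <- .expand_profile_field(profile$fpr, labels, "fpr")

  # truth membership and grades as n x L matrices
  truth_mat <- matrix(FALSE, n, L)
  truth_grade <- matrix("unspecified", n, L)
  for (i in seq_len(n)) {
    tr <- cohort$truth[[i]]
    idx <- match(canonical_label(tr$label), canonical_label(labels))
    truth_mat[i, idx] <- TRUE
    truth_grade[i, idx] <- tr$grade
  }
  pmat <- matrix(rep(fpr, each = n), n, L)
  pmat[truth_mat] <- matrix(rep(sens, each = n), n, L)[truth_mat]

  .with_seed(seed, {
    base <- matrix(stats::runif(n * L), n, L) < pmat
    rows <- vector("list", n * n_runs)
    k <- 0
    for (r in seq_len(n_runs)) {
      if (r == 1) {
        verdict <- base
      } else {
        flip <- matrix(stats::runif(n * L), n, L) < profile$run_flip
        fresh <- matrix(stats::runif(n * L), n, L) < pmat
        verdict <- ifelse(flip, fresh, base)
      }
      grade_r <- truth_grade
      # grades for false positives: drawn from the severity distribution
      fp_cells <- which(verdict & !truth_mat, arr.ind = TRUE)
      if (nrow(fp_cells) > 0) {
        for (j in unique(fp_cells[, 2])) {
          ii <- fp_cells[fp_cells[, 2] == j, 1]
          grade_r[ii, j] <- if (graded[j]) {
            sample(SEVERITY_GRADES, length(ii), replace = TRUE,
                   prob = c(sd_rows$mild[j], sd_rows$moderate[j],
                            sd_rows$severe[j]))
          } else "unspecified"
        }
      }
      # severity confusion on detected true labels (graded labels only)
      tp_cells <- which(verdict & truth_mat, arr.ind = TRUE)
      if (nrow(tp_cells) > 0 && profile$severity_confusion > 0) {
        confuse <- stats::runif(nrow(tp_cells)) < profile$severity_confusion
        for (m in which(confuse)) {
          i <- tp_cells[m, 1]; j <- tp_cells[m, 2]
          if (graded[j]) {
            others <- setdiff(SEVERITY_GRADES, truth_grade[i, j])
            grade_r[i, j] <- sample(others, 1)
          }
        }
      }
      for (i in seq_len(n)) {
        k <- k + 1
        j <- which(verdict[i, ])
        rows[[k]] <- list(case_id = cohort$case_id[i], run = r,
                          diagnoses = diagnosis_set(labels[j], grade_r[i, j]))
      }
    }
    out <- tibble::tibble(
      case_id = vapply(rows, `[[`, character(1), "case_id"),
      source = source,
      run = vapply(rows, `[[`, integer(1), "run"),
      diagnoses = lapply(rows, `[[`, "diagnoses")
    )
    dplyr::arrange(out, .data$case_id, .data$run)
  })
}

#' Generate independent rater annotations
#'
#' Each rater annotates every case once, independently conditional on the
#' truth, according to their own profile. Used to exercise agreement and
#' consensus procedures.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param n_raters number of raters (>= 2; agreement is undefined below that).
#' @param rater_profiles list of [predictor_profile()]s, one per rater;
#'   default: identical accurate raters (sensitivity 0.9, fpr 0.02).
#' @param seed integer seed.
#' @return tibble with columns `rater`, `case_id`, `diagnoses` (list-column).
#' @export
generate_rater_annotations <- function(cohort, n_raters = 3,
                                       rater_profiles = NULL, seed = 1L) {
  if (n_raters < 2) {
    stop("n_raters must be >= 2: agreement is undefined for one rater",
         call. = FALSE)
  }
  if (is.null(rater_profiles)) {
    rater_profiles <- replicate(
      n_raters,
      predictor_profile(sensitivity = 0.9, fpr = 0.02,
                        severity_confusion = 0.05, run_flip = 0),
      simplify = FALSE
    )
  }
  if (length(rater_profiles) != n_raters) {
    stop("need one profile per rater", call. = FALSE)
  }
  .with_seed(seed, {
    per_rater <- lapply(seq_len(n_raters), function(r) {
      p <- generate_predictions(cohort, rater_profiles[[r]], n_runs = 1,
                                seed = sample.int(.Machine$integer.max, 1),
                                source = paste0("rater", r))
      tibble::tibble(rater = paste0("rater", r), case_id = p$case_id,
                     diagnoses = p$diagnoses)
    })
    dplyr::bind_rows(per_rater)
  })
}

#' Serialize predictions to raw structured-output text
#'
#' Renders each (case, run) prediction as the structured JSON output dialect,
#' optionally with a "think" reasoning field, and corrupts a controlled
#' fraction of records (truncation or stray prose) to exercise the parser's
#' failure path.
#'
#' @param predictions tibble from [generate_predictions()].
#' @param with_think include a non-empty reasoning field in each record.
#' @param malformed_fraction fraction of records to corrupt, in \[0,1\].
#' @param seed integer seed for choosing which records are corrupted.
#' @param schema output schema field names, see [output_schema()].
#' @return tibble `case_id`, `source`, `run`, `raw` (character), `corrupted`.
#' @export
generate_raw_outputs <- function(predictions, with_think = FALSE,
                                 malformed_fraction = 0, seed = 1L,
                                 schema = output_schema()) {
  if (malformed_fraction < 0 || malformed_fraction > 1) {
    stop("malformed_fraction must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(predictions)
  .with_seed(seed, {
    raw <- vapply(seq_len(n), function(i) {
      think <- if (with_think) {
        paste0("case ", predictions$case_id[i],
               ": reviewed records and graded findings")
      } else NULL
      serialize_model_output(predictions$diagnoses[[i]], think = think,
                             schema = schema)
    }, character(1))
    n_bad <- round(malformed_fraction * n)
    bad <- if (n_bad > 0) sample.int(n, n_bad) else integer(0)
    if (length(bad) > 0) {
      mode <- sample(c("truncate", "stray"), length(bad), replace = TRUE)
      raw[bad] <- ifelse(
        mode == "truncate",
        substr(raw[bad], 1, pmax(1, nchar(raw[bad]) %/% 2)),
        paste0("The assessment concluded without structured output. ",
               "See narrative above.")
      )
    }
    tibble::tibble(case_id = predictions$case_id, source = predictions$source,
                   run = predictions$run, raw = raw,
                   corrupted = seq_len(n) %in% bad)
  })
}
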