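test_that("cohort generation is deterministic and respects the spec", {
  spec <- cohort_spec(n_patients = 60, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 60)
  expect_true(all(a$token_count >= 1))
  expect_true(all(a$pdqi_score >= 1 & a$pdqi_score <= 5))
  expect_true(all(vapply(a$truth, function(d) !anyDuplicated(d$label), logical(1))))
})

test_that("zero prevalence yields empty truth everywhere", {
  ls <- tiny_label_set(3)
  spec <- cohort_spec(
    n_patients = 15, label_set = ls,
    label_prevalence = tibble::tibble(label = ls$label, center1 = 0, center2 = 0),
    severity_dist = default_severity_dist(ls), seed = 2
  )
  cohort <- generate_cohort(spec)
  expect_true(all(vapply(cohort$truth, nrow, integer(1)) == 0))
})

test_that("per-label counts stay within binomial 99% bounds", {
  spec <- cohort_spec(n_patients = 146, seed = 7)
  cohort <- generate_cohort(spec)
  lp <- spec$label_prevalence
  mix <- spec$center_mix
  # the coherence rule thins "infection of unknown source" truth by the
  # probability that no specific infection co-occurs (independent sampling)
  spec_inf <- lp$label %in% default_specific_infections()
  keep1 <- prod(1 - lp$center1[spec_inf])
  keep2 <- prod(1 - lp$center2[spec_inf])
  eff1 <- lp$center1
  eff2 <- lp$center2
  iu <- lp$label == "infection of unknown source"
  eff1[iu] <- eff1[iu] * keep1
  eff2[iu] <- eff2[iu] * keep2
  marginal <- mix[["center1"]] * eff1 + mix[["center2"]] * eff2
  counts <- table(factor(
    unlist(lapply(cohort$truth, function(d) d$label)),
    levels = lp$label
  ))
  for (j in seq_along(lp$label)) {
    lo <- qbinom(0.005, 146, marginal[j])
    hi <- qbinom(0.995, 146, marginal[j])
    expect_gte(as.integer(counts[j]), lo)
    expect_lte(as.integer(counts[j]), hi)
  }
})

test_that("invalid specs fail naming the offending field", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(center_mix = c(center1 = 0.7, center2 = 0.7)),
               "center_mix")
  ls <- tiny_label_set(2)
  expect_error(
    cohort_spec(label_set = ls,
                label_prevalence = tibble::tibble(label = ls$label,
                                                  center1 = 1.4, center2 = 0),
                severity_dist = default_severity_dist(ls)),
    "label_prevalence")
  expect_error(
    cohort_spec(label_set = ls,
                label_prevalence = tibble::tibble(label = ls$label,
                                                  center1 = .1, center2 = .1),
                severity_dist = tibble::tibble(label = ls$label, mild = 0.9,
                                               moderate = 0.3, severe = 0.2)),
    "severity_dist")
})

test_that("perfect and null predictors hit their limits", {
  cohort <- tiny_cohort(12, seed = 3)
  perfect <- predictor_profile(sensitivity = 1, fpr = 0,
                               severity_confusion = 0, run_flip = 0)
  preds <- generate_predictions(cohort, perfect, n_runs = 3, seed = 4)
  for (i in seq_len(nrow(preds))) {
    truth <- cohort$truth[[match(preds$case_id[i], cohort$case_id)]]
    expect_equal(dplyr::arrange(preds$diagnoses[[i]], label),
                 dplyr::arrange(truth, label))
  }
  null <- predictor_profile(sensitivity = 0, fpr = 0)
  empty <- generate_predictions(cohort, null, n_runs = 2, seed = 4)
  expect_true(all(vapply(empty$diagnoses, nrow, integer(1)) == 0))
})

test_that("prediction generation recovers profile parameters at n = 500", {
  cohort <- generate_cohort(cohort_spec(n_patients = 500, seed = 21))
  profile <- predictor_profile(sensitivity = 0.8, fpr = 0.05,
                               severity_confusion = 0, run_flip = 0.1)
  preds <- generate_predictions(cohort, profile, n_runs = 2, seed = 22)
  labels <- canonical_label(default_label_set()$label)
  for (r in 1:2) {
    prun <- preds[preds$run == r, ]
    n_true <- 0; n_hit <- 0; n_absent <- 0; n_fp <- 0
    for (i in seq_len(nrow(prun))) {
      truth <- cohort$truth[[match(prun$case_id[i], cohort$case_id)]]
      tl <- canonical_label(truth$label)
      pl <- canonical_label(prun$diagnoses[[i]]$label)
      n_true <- n_true + length(tl)
      n_hit <- n_hit + sum(tl %in% pl)
      n_absent <- n_absent + length(labels) - length(tl)
      n_fp <- n_fp + sum(!pl %in% tl)
    }
    se_sens <- sqrt(0.8 * 0.2 / n_true)
    expect_lt(abs(n_hit / n_true - 0.8), 3 * se_sens)
    # 3 standard errors of the false-positive rate
    se <- sqrt(0.05 * 0.95 / n_absent)
    expect_lt(abs(n_fp / n_absent - 0.05), 3 * se + 1e-9)
  }
})

test_that("profiles referencing unknown labels are rejected", {
  cohort <- tiny_cohort(5, seed = 1, k_labels = 3)
  bad <- predictor_profile(sensitivity = c("not a label" = 0.9), fpr = 0.05)
  expect_error(generate_predictions(cohort, bad, n_runs = 1, seed = 1),
               "absent from the cohort label set")
})

test_that("ai_like and human_like styles produce their recall/precision signatures", {
  cohort <- generate_cohort(cohort_spec(n_patients = 500, seed = 31))
  ai <- evaluate_predictions(
    cohort,
    generate_predictions(cohort, predictor_profile(style = "ai_like"),
                         n_runs = 1, seed = 32),
    modes = "micro")
  human <- evaluate_predictions(
    cohort,
    generate_predictions(cohort, predictor_profile(style = "human_like"),
                         n_runs = 1, seed = 33),
    modes = "micro")
  expect_gt(ai$recall, ai$precision)
  expect_gt(human$precision, human$recall)
})

test_that("rater annotations: perfect raters agree; fewer than two is an error", {
  cohort <- tiny_cohort(10, seed = 8)
  perfect <- replicate(3, predictor_profile(sensitivity = 1, fpr = 0,
                                            severity_confusion = 0,
                                            run_flip = 0),
                       simplify = FALSE)
  ann <- generate_rater_annotations(cohort, 3, perfect, seed = 5)
  wide <- split(ann, ann$rater)
  for (cid in cohort$case_id) {
    sets <- lapply(wide, function(w) {
      dplyr::arrange(w$diagnoses[[match(cid, w$case_id)]], label)
    })
    expect_identical(sets[[1]], sets[[2]])
    expect_identical(sets[[2]], sets[[3]])
  }
  expect_error(generate_rater_annotations(cohort, 1, seed = 1), "undefined")
})

test_that("raw outputs round-trip through the parser; corruption breaks them", {
  cohort <- tiny_cohort(8, seed = 9)
  preds <- generate_predictions(cohort, predictor_profile(style = "ai_like"),
                                n_runs = 2, seed = 10)
  clean <- generate_raw_outputs(preds, with_think = TRUE,
                                malformed_fraction = 0, seed = 1)
  for (i in seq_len(nrow(clean))) {
    res <- parse_model_output(clean$raw[i], expect_think = TRUE)
    expect_equal(res$status, "ok")
    expect_true(nzchar(res$think))
    expect_equal(dplyr::arrange(res$diagnoses, label),
                 dplyr::arrange(preds$diagnoses[[i]], label))
  }
  broken <- generate_raw_outputs(preds, malformed_fraction = 1, seed = 2)
  status <- vapply(broken$raw,
                   function(r) parse_model_output(r)$status, character(1))
  expect_true(all(status == "failed"))
})
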