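test_that("Bonferroni correction reproduces the worked values and caps at 1", {
  expect_equal(bonferroni(0.0055, 2), 0.011)
  expect_equal(bonferroni(0.602, 2), 1.000)
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_equal(bonferroni(c(0.01, 0.9), 3), c(0.03, 1))
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
})

test_that("t interval matches the closed form", {
  ident <- t_interval(rep(0.7, 5))
  expect_equal(ident$lo, 0.7)
  expect_equal(ident$hi, 0.7)

  tw <- t_interval(c(0, 1), level = 0.95)
  half <- qt(0.975, df = 1) * sd(c(0, 1)) / sqrt(2)
  expect_equal(tw$mean, 0.5)
  expect_equal(tw$hi - tw$mean, half)
  expect_equal(half, 6.353102, tolerance = 1e-6)

  # width shrinks as 1/sqrt(R) for fixed sd
  v4 <- c(0.6, 0.8, 0.6, 0.8)
  v8 <- rep(v4, 2)
  expect_lt(t_interval(v8)$hi - t_interval(v8)$lo,
            t_interval(v4)$hi - t_interval(v4)$lo)
  expect_error(t_interval(0.5), "at least 2")
})

test_that("bootstrap null identity: identical runs give zero diff and p = 1", {
  cohort <- tiny_cohort(20, seed = 41)
  runs <- truth_echo_predictions(cohort, n_runs = 3)
  # perturb away from perfection so per-case metrics are not all 1
  bt <- bootstrap_paired_test(cohort, runs, runs, metric = "f1",
                              config = bootstrap_config(iterations = 200,
                                                        seed = 5))
  expect_equal(bt$mean_diff, 0)
  expect_equal(bt$p, 1)
  expect_equal(bt$p_corrected, 1)
  expect_true(bt$ci_low <= bt$mean_diff && bt$mean_diff <= bt$ci_high)
})

test_that("bootstrap results are deterministic under seed, p has 1/B granularity", {
  cohort <- tiny_cohort(30, seed = 42)
  a <- generate_predictions(cohort, predictor_profile(sensitivity = 0.7,
                                                      fpr = 0.05),
                            n_runs = 3, seed = 1, source = "A")
  b <- generate_predictions(cohort, predictor_profile(sensitivity = 0.85,
                                                      fpr = 0.03),
                            n_runs = 3, seed = 2, source = "B")
  cfg <- bootstrap_config(iterations = 400, seed = 77)
  bt1 <- bootstrap_paired_test(cohort, a, b, config = cfg)
  bt2 <- bootstrap_paired_test(cohort, a, b, config = cfg)
  expect_identical(bt1$diffs, bt2$diffs)
  expect_identical(tidy(bt1), tidy(bt2))
  expect_equal(bt1$p * 400, round(bt1$p * 400))
  expect_equal(bt1$p_corrected, min(1, 2 * bt1$p))
  expect_true(bt1$ci_low <= bt1$mean_diff && bt1$mean_diff <= bt1$ci_high)

  expect_warning(
    bootstrap_paired_test(cohort, a, b,
                          config = bootstrap_config(iterations = 50, seed = 1)),
    "unreliable")
  expect_error(
    bootstrap_paired_test(cohort[-1, ], a, b, config = cfg),
    "cover exactly")
})

test_that("tidy and glance summarize a comparison", {
  cohort <- tiny_cohort(15, seed = 43)
  a <- generate_predictions(cohort, predictor_profile(sensitivity = 0.6,
                                                      fpr = 0.05),
                            n_runs = 2, seed = 3, source = "A")
  b <- truth_echo_predictions(cohort, n_runs = 2, source = "B")
  bt <- bootstrap_paired_test(cohort, a, b,
                              config = bootstrap_config(iterations = 200,
                                                        seed = 9))
  td <- tidy(bt)
  expect_named(td, c("metric", "mode", "strict", "mean_diff", "ci_low",
                     "ci_high", "p", "p_corrected"))
  gl <- glance(bt)
  expect_equal(gl$B, 200)
  expect_type(gl$significant, "logical")
})

test_that("Fleiss kappa: perfect agreement, hand-computed toy, chance level", {
  ls <- tiny_label_set(5)
  cohort <- tiny_cohort(12, seed = 51, k_labels = 5)
  perfect <- replicate(3, predictor_profile(sensitivity = 1, fpr = 0,
                                            severity_confusion = 0,
                                            run_flip = 0), simplify = FALSE)
  ann <- generate_rater_annotations(cohort, 3, perfect, seed = 6)
  k <- fleiss_kappa(ann, ls, ci = FALSE)
  expect_equal(k$kappa, 1)

  # 2 raters x 1 case x 3 labels: items (both present, both absent, split)
  # P_i = (1, 1, 0), P-bar = 2/3, p_present = 1/2, P_e = 1/2, kappa = 1/3
  toy_ls <- tibble::tibble(label = c("A", "B", "C"), graded = FALSE)
  toy <- tibble::tibble(
    rater = c("r1", "r2"),
    case_id = c("c1", "c1"),
    diagnoses = list(diagnosis_set(c("A", "C")), diagnosis_set("A"))
  )
  kt <- fleiss_kappa(toy, toy_ls, ci = FALSE)
  expect_equal(kt$kappa, 1 / 3, tolerance = 1e-12)
  expect_equal(kt$n_items, 3)

  # independent coin-flip raters: kappa near zero over 1000 pooled items
  flip_ls <- tiny_label_set(10)
  flip_cohort <- tiny_cohort(100, seed = 52, k_labels = 10)
  flips <- replicate(2, predictor_profile(sensitivity = 0.5, fpr = 0.5,
                                          run_flip = 0), simplify = FALSE)
  flip_ann <- generate_rater_annotations(flip_cohort, 2, flips, seed = 7)
  kf <- fleiss_kappa(flip_ann, flip_ls, ci = FALSE)
  expect_lt(abs(kf$kappa), 0.1)

  # bootstrap CI brackets the point estimate and is ordered
  ann3 <- generate_rater_annotations(cohort, 3, seed = 8)
  kc <- fleiss_kappa(ann3, ls, ci = TRUE, B = 200, seed = 3)
  expect_lte(kc$ci_low, kc$ci_high)
  expect_lte(kc$kappa, 1)
  expect_named(tidy(kc), c("kappa", "ci_low", "ci_high"))

  # raters over different case sets are rejected
  bad <- toy
  bad$case_id <- c("c1", "c2")
  expect_error(fleiss_kappa(bad, toy_ls), "different case sets")
})

test_that("consensus gold keeps >=threshold labels with majority grades", {
  ls <- tibble::tibble(label = c("pneumonia", "acute kidney injury"),
                       graded = TRUE)
  ann <- tibble::tibble(
    rater = rep(c("r1", "r2", "r3"), each = 1),
    case_id = "c1",
    diagnoses = list(
      diagnosis_set("pneumonia", "mild"),
      diagnosis_set(c("pneumonia", "acute kidney injury"),
                    c("mild", "severe")),
      diagnosis_set()
    )
  )
  gold <- consensus_gold(ann, threshold = 2, label_set = ls)
  expect_equal(gold$diagnoses[[1]]$label, "pneumonia")
  expect_equal(gold$diagnoses[[1]]$grade, "mild")

  # grade tie (mild vs moderate, third rater absent) -> more severe + flag
  tie <- tibble::tibble(
    rater = c("r1", "r2", "r3"),
    case_id = "c1",
    diagnoses = list(
      diagnosis_set("pneumonia", "mild"),
      diagnosis_set("pneumonia", "moderate"),
      diagnosis_set()
    )
  )
  gt <- consensus_gold(tie, threshold = 2, label_set = ls)
  expect_equal(gt$diagnoses[[1]]$grade, "moderate")
  expect_equal(gt$grade_tie_labels[[1]], "pneumonia")

  expect_error(consensus_gold(tie, threshold = 4, label_set = ls),
               "exceeds")
})

test_that("consensus gold equals majority vote on simulated panels", {
  cohort <- tiny_cohort(30, seed = 53)
  ann <- generate_rater_annotations(cohort, 3, seed = 9)
  gold <- consensus_gold(ann, threshold = 2)
  for (i in seq_len(nrow(gold))) {
    cid <- gold$case_id[i]
    votes <- table(unlist(lapply(
      ann$diagnoses[ann$case_id == cid],
      function(d) unique(canonical_label(d$label)))))
    majority <- names(votes)[votes >= 2]
    if (is.null(majority)) majority <- character(0)
    expect_setequal(canonical_label(gold$diagnoses[[i]]$label), majority)
  }
})
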