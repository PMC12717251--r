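test_that("targeted decomposition yields one unit per label with shared text", {
  ls22 <- default_label_set()
  units <- decompose_targeted("case_0001", "record text", ls22)
  expect_equal(nrow(units), 22)
  expect_equal(length(unique(units$target_label)), 22)
  expect_true(all(units$record_text == "record text"))

  one <- decompose_targeted("c", "t", tiny_label_set(1))
  expect_equal(nrow(one), 1)
  expect_error(decompose_targeted("c", "t", tiny_label_set(0)), "non-empty")
})

test_that("aggregation rule 1: all-negative verdicts collapse to the sentinel", {
  ls <- default_label_set()
  verdicts <- tibble::tibble(label = ls$label, present = FALSE,
                             grade = "unspecified")
  out <- aggregate_targeted(verdicts, ls)
  expect_equal(nrow(out), 0)
  expect_true(attr(out, "sentinel"))
})

test_that("aggregation rule 2: specific infections suppress unknown-source", {
  ls <- default_label_set()
  verdicts <- tibble::tibble(label = ls$label, present = FALSE,
                             grade = "unspecified")
  v2 <- verdicts
  v2$present[v2$label %in% c("pneumonia", "infection of unknown source")] <- TRUE
  v2$grade[v2$label == "pneumonia"] <- "moderate"
  out <- aggregate_targeted(v2, ls)
  expect_equal(out$label, "pneumonia")

  # unknown source alone survives
  v3 <- verdicts
  v3$present[v3$label == "infection of unknown source"] <- TRUE
  out3 <- aggregate_targeted(v3, ls)
  expect_equal(out3$label, "infection of unknown source")
  expect_false(attr(out3, "sentinel"))

  # never both in an output, for any verdict pattern
  set.seed(44)
  for (i in 1:20) {
    v <- verdicts
    v$present <- runif(nrow(v)) < 0.3
    out <- aggregate_targeted(v, ls)
    if (any(canonical_label(out$label) %in%
            canonical_label(default_specific_infections()))) {
      expect_false("infection of unknown source" %in% out$label)
    }
  }

  expect_error(aggregate_targeted(verdicts[-1, ], ls), "missing verdicts")
})

test_that("comprehensive and targeted agree under a truth-echo predictor", {
  cohort <- tiny_cohort(25, seed = 13)
  predictor <- truth_echo_predictor(cohort)
  ls <- attr(cohort, "label_set")
  texts <- case_record_text(cohort)
  for (i in seq_len(nrow(cohort))) {
    comp <- run_comprehensive(cohort$case_id[i], texts[i], predictor, ls)
    targ <- run_targeted(cohort$case_id[i], texts[i], predictor, ls)
    targ_d <- targ$diagnoses
    attr(targ_d, "sentinel") <- NULL
    expect_equal(dplyr::arrange(comp$diagnoses, label),
                 dplyr::arrange(targ_d, label))
    expect_equal(comp$n_calls, 1)
    expect_equal(targ$n_calls, nrow(ls))
    expect_false(comp$parse_failed)
  }
})

test_that("sentinel outputs and parse failures are recorded, never silent", {
  cohort <- tiny_cohort(4, seed = 14)
  ls <- attr(cohort, "label_set")
  sentinel_pred <- function(...) serialize_model_output(diagnosis_set())
  res <- run_comprehensive("x", "t", sentinel_pred, ls)
  expect_equal(nrow(res$diagnoses), 0)
  expect_true(res$sentinel)

  broken_pred <- function(...) "not json at all"
  fail <- run_comprehensive("x", "t", broken_pred, ls, retries = 0)
  expect_true(fail$parse_failed)
  expect_equal(nrow(fail$diagnoses), 0)
  expect_equal(fail$n_calls, 1)

  # targeted: every unit fails -> sentinel plus per-label failure flags
  tfail <- run_targeted("x", "t", broken_pred, ls, retries = 0)
  expect_true(tfail$sentinel)
  expect_true(all(tfail$verdicts$parse_failed))
  expect_equal(nrow(tfail$verdicts), nrow(ls))

  # retry budget: succeed on the second attempt
  calls <- 0
  flaky <- function(...) {
    calls <<- calls + 1
    if (calls < 2) "garbage" else serialize_model_output(
      diagnosis_set("pneumonia", "mild"))
  }
  ok <- run_comprehensive("x", "t", flaky, default_label_set(), retries = 2)
  expect_false(ok$parse_failed)
  expect_equal(ok$n_calls, 2)
})

test_that("training expansion is exactly cases x labels and conserves truth", {
  cohort <- generate_cohort(cohort_spec(n_patients = 146, seed = 7))
  ex <- expand_training_examples(cohort)
  expect_equal(nrow(ex), 146 * 22)

  # per-label positive counts equal the cohort's per-label truth counts
  truth_counts <- table(factor(
    unlist(lapply(cohort$truth, function(d) d$label)),
    levels = default_label_set()$label))
  pos_counts <- table(factor(ex$target_label[ex$present],
                             levels = default_label_set()$label))
  expect_equal(as.integer(pos_counts), as.integer(truth_counts))

  # single case with empty truth -> all negative examples
  ls <- default_label_set()
  one <- tibble::tibble(case_id = "c1", truth = list(diagnosis_set()))
  ex1 <- expand_training_examples(one, ls)
  expect_equal(nrow(ex1), 22)
  expect_false(any(ex1$present))
})

test_that("parsing validates structure and flags content problems", {
  ok <- parse_model_output(
    '{"complications":[{"complication":"pneumonia","severity":"moderate"}]}')
  expect_equal(ok$status, "ok")
  expect_equal(ok$diagnoses$label, "pneumonia")
  expect_equal(ok$diagnoses$grade, "moderate")

  sent <- parse_model_output(
    '{"complications":[{"complication":"no postoperative complications"}]}')
  expect_equal(sent$status, "ok")
  expect_equal(nrow(sent$diagnoses), 0)
  expect_true(sent$sentinel)

  trunc <- parse_model_output('{"complications":[{"complica')
  expect_equal(trunc$status, "failed")

  # unknown labels flagged when a label set is supplied, not fatal
  res <- parse_model_output(
    '{"complications":[{"complication":"made-up syndrome","severity":"mild"},
      {"complication":"pneumonia","severity":"mild"}]}',
    label_set = default_label_set())
  expect_equal(res$status, "ok")
  expect_equal(res$unknown_labels, "made-up syndrome")
  expect_equal(res$diagnoses$label, "pneumonia")

  # grades normalized; junk grades become unspecified
  odd <- parse_model_output(
    '{"complications":[{"complication":"pneumonia","severity":"Mild "}]}')
  expect_equal(odd$diagnoses$grade, "mild")
  junk <- parse_model_output(
    '{"complications":[{"complication":"pneumonia","severity":"grade IV"}]}')
  expect_equal(junk$diagnoses$grade, "unspecified")

  # think field required only when expected
  nothink <- parse_model_output(
    '{"complications":[{"complication":"pneumonia","severity":"mild"}]}',
    expect_think = TRUE)
  expect_equal(nothink$status, "failed")
})

test_that("serialize and parse are mutually inverse on well-formed records", {
  set.seed(71)
  for (i in 1:20) {
    inst <- random_instance(1)
    d <- suppressWarnings(normalize_diagnoses(inst$gold[[1]], strict = TRUE))
    d <- diagnosis_set(d$label, d$grade)
    raw <- serialize_model_output(d, think = "reasoning")
    back <- parse_model_output(raw, expect_think = TRUE)
    expect_equal(back$status, "ok")
    expect_equal(dplyr::arrange(back$diagnoses, label),
                 dplyr::arrange(d, label))
  }
})

test_that("run_strategy produces predictions plus an auditable manifest", {
  cohort <- tiny_cohort(6, seed = 15)
  predictor <- truth_echo_predictor(cohort)
  out <- run_strategy(cohort, predictor, "targeted", run = 2, source = "t")
  expect_equal(nrow(out$predictions), 6)
  expect_equal(unique(out$predictions$run), 2L)
  expect_equal(out$manifest$n_calls,
               rep(nrow(attr(cohort, "label_set")), 6))
  expect_false(any(out$manifest$parse_failed))
  res <- evaluate_predictions(cohort, out$predictions, modes = "micro")
  expect_equal(res$f1, 1)

  # manifests serialize one line per (case, strategy, run)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_manifest_jsonl(out$manifest, path)
  expect_length(readLines(path), 6)

  # a half-broken predictor leaves negative flagged verdicts
  first_label <- canonical_label(attr(cohort, "label_set")$label[1])
  flaky <- function(record_text, labels, mode, cot) {
    if (identical(mode, "targeted") &&
        canonical_label(labels)[1] == first_label) "garbage"
    else truth_echo_predictor(cohort)(record_text, labels, mode, cot)
  }
  broken <- run_strategy(cohort, flaky, "targeted", retries = 0)
  expect_true(all(broken$manifest$n_failed_units == 1))
  expect_true(all(broken$manifest$parse_failed))
})
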