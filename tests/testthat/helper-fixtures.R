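# shared small fixtures built in code

tiny_label_set <- function(k = 4, graded = TRUE) {
  tibble::tibble(label = paste0("cmp", seq_len(k)),
                 graded = rep_len(graded, k))
}

tiny_cohort <- function(n = 10, seed = 1, k_labels = NULL) {
  if (is.null(k_labels)) {
    generate_cohort(cohort_spec(n_patients = n, seed = seed))
  } else {
    ls <- tiny_label_set(k_labels)
    generate_cohort(cohort_spec(
      n_patients = n, label_set = ls,
      label_prevalence = tibble::tibble(label = ls$label,
                                        center1 = 0.3, center2 = 0.3),
      severity_dist = default_severity_dist(ls),
      seed = seed
    ))
  }
}

# predictions table echoing the cohort truth exactly, for n_runs runs
truth_echo_predictions <- function(cohort, n_runs = 1, source = "echo") {
  tidyr::crossing(case_id = cohort$case_id, run = seq_len(n_runs)) |>
    dplyr::mutate(
      source = source,
      diagnoses = cohort$truth[match(case_id, cohort$case_id)]
    ) |>
    dplyr::select(case_id, source, run, diagnoses)
}

example_record <- function() {
  clinical_record(
    general_info = "adult patient, elective laparotomy",
    postop_notes = data.frame(
      date = c("2024-02-01", "2024-02-03", "2024-02-06"),
      text = c("day 0 extubated", "fever and distension", "improving")),
    abnormal_labs = data.frame(date = c("2024-02-02", "2024-02-05"),
                               text = c("WBC 14.2", "creatinine 180")),
    exam_reports = data.frame(date = "2024-02-04",
                              text = "CT: fluid collection"),
    identifiers = c("name: redacted", "MRN 0012345")
  )
}

all_record_dates <- function(rec) {
  c(rec$postop_notes$date, rec$abnormal_labs$date, rec$exam_reports$date)
}
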