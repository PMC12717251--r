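#' File-format plumbing and pipeline entry points
#'
#' JSONL readers/writers for cases, predictions and annotations; a
#' serializable run configuration; and the four pipeline stages
#' (simulate, evaluate, compare, stratify) that bind the modules together.
#' Every output carries the resolved configuration hash, and each stage logs
#' one structured line with its counts so failure-flag conventions stay
#' auditable.
#'
#' @name pipeline
NULL

.SCHEMA_VERSION <- 1L

# small polynomial rolling hash so outputs can carry a config fingerprint
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
  h <- 0
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

.diag_to_list <- function(d) {
  lapply(seq_len(nrow(d)), function(i) {
    list(label = d$label[i], grade = d$grade[i])
  })
}

.diag_from_list <- function(x) {
  if (length(x) == 0) return(diagnosis_set())
  diagnosis_set(vapply(x, `[[`, character(1), "label"),
                vapply(x, `[[`, character(1), "grade"))
}

.write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), con)
  }
  invisible(path)
}

.read_jsonl <- function(path, required_fields) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec)) {
      stop("malformed JSONL at ", basename(path), " line ", i, call. = FALSE)
    }
    missing <- setdiff(required_fields, names(rec))
    if (length(missing) > 0) {
      stop("missing field(s) ", paste(missing, collapse = ", "), " at ",
           basename(path), " line ", i, call. = FALSE)
    }
    rec
  })
}

#' Write / read a cohort as JSONL
#'
#' One case per line with its center, truth set, token count and quality
#' score; the label set travels in a sidecar attribute line-free form (it is
#' part of the run config, not the data file).
#'
#' @param cohort cohort tibble.
#' @param path file path.
#' @return `path` (writer) or the cohort tibble (reader).
#' @export
write_cases_jsonl <- function(cohort, path) {
  recs <- lapply(seq_len(nrow(cohort)), function(i) {
    list(schema_version = .SCHEMA_VERSION,
         case_id = cohort$case_id[i], center = cohort$center[i],
         token_count = cohort$token_count[i],
         pdqi_score = cohort$pdqi_score[i],
         truth = .diag_to_list(cohort$truth[[i]]))
  })
  .write_jsonl(recs, path)
}

#' @rdname write_cases_jsonl
#' @export
read_cases_jsonl <- function(path) {
  recs <- .read_jsonl(path, c("case_id", "center", "truth"))
  tibble::tibble(
    case_id = vapply(recs, `[[`, character(1), "case_id"),
    center = vapply(recs, `[[`, character(1), "center"),
    truth = lapply(recs, function(r) .diag_from_list(r$truth)),
    token_count = vapply(recs, function(r) {
      as.integer(r$token_count %||% NA_integer_)
    }, integer(1)),
    pdqi_score = vapply(recs, function(r) {
      as.numeric(r$pdqi_score %||% NA_real_)
    }, numeric(1))
  )
}

#' Write / read prediction runs as JSONL
#'
#' One (case, source, run) prediction set per line.
#'
#' @param predictions predictions tibble.
#' @param path file path.
#' @return `path` (writer) or the predictions tibble (reader).
#' @export
write_predictions_jsonl <- function(predictions, path) {
  recs <- lapply(seq_len(nrow(predictions)), function(i) {
    list(schema_version = .SCHEMA_VERSION,
         case_id = predictions$case_id[i], source = predictions$source[i],
         run = predictions$run[i],
         diagnoses = .diag_to_list(predictions$diagnoses[[i]]))
  })
  .write_jsonl(recs, path)
}

#' @rdname write_predictions_jsonl
#' @export
read_predictions_jsonl <- function(path) {
  recs <- .read_jsonl(path, c("case_id", "source", "run", "diagnoses"))
  tibble::tibble(
    case_id = vapply(recs, `[[`, character(1), "case_id"),
    source = vapply(recs, `[[`, character(1), "source"),
    run = vapply(recs, function(r) as.integer(r$run), integer(1)),
    diagnoses = lapply(recs, function(r) .diag_from_list(r$diagnoses))
  )
}

#' Write / read rater annotations as JSONL
#'
#' @param annotations annotations tibble (`rater`, `case_id`, `diagnoses`).
#' @param path file path.
#' @return `path` (writer) or the annotations tibble (reader).
#' @export
write_annotations_jsonl <- function(annotations, path) {
  recs <- lapply(seq_len(nrow(annotations)), function(i) {
    list(schema_version = .SCHEMA_VERSION,
         rater = annotations$rater[i], case_id = annotations$case_id[i],
         diagnoses = .diag_to_list(annotations$diagnoses[[i]]))
  })
  .write_jsonl(recs, path)
}

#' @rdname write_annotations_jsonl
#' @export
read_annotations_jsonl <- function(path) {
  recs <- .read_jsonl(path, c("rater", "case_id", "diagnoses"))
  tibble::tibble(
    rater = vapply(recs, `[[`, character(1), "rater"),
    case_id = vapply(recs, `[[`, character(1), "case_id"),
    diagnoses = lapply(recs, function(r) .diag_from_list(r$diagnoses))
  )
}

#' Run configuration
#'
#' Everything a full pipeline run needs, fully serializable to YAML so the
#' resolved configuration can be written beside every output.
#'
#' @param cohort a [cohort_spec()].
#' @param profiles named list of [predictor_profile()]s to simulate.
#' @param n_runs repeated inference runs per predictor.
#' @param modes metric modes, subset of micro/macro.
#' @param strict logical vector of strict settings to evaluate.
#' @param bootstrap a [bootstrap_config()].
#' @param schemes stratification schemes to run.
#' @param seed master seed for the run.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       profiles = list(ai = predictor_profile(style = "ai_like"),
                                       human = predictor_profile(style = "human_like")),
                       n_runs = 5,
                       modes = c("micro", "macro"),
                       strict = c(FALSE, TRUE),
                       bootstrap = bootstrap_config(),
                       schemes = c("token_quartile", "complication_count",
                                   "pdqi_quality"),
                       seed = 1L) {
  structure(list(cohort = cohort, profiles = profiles, n_runs = n_runs,
                 modes = modes, strict = strict, bootstrap = bootstrap,
                 schemes = schemes, seed = seed),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path` (writer) or a `run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  ser <- rapply(unclass(config), function(x) x, how = "list")
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- raw$cohort
  cohort <- cohort_spec(
    n_patients = spec$n_patients,
    center_mix = unlist(spec$center_mix),
    label_set = tibble::as_tibble(spec$label_set),
    label_prevalence = tibble::as_tibble(spec$label_prevalence),
    severity_dist = tibble::as_tibble(spec$severity_dist),
    token_count_dist = spec$token_count_dist,
    pdqi_dist = spec$pdqi_dist,
    enforce_infection_exclusivity = isTRUE(spec$enforce_infection_exclusivity),
    seed = spec$seed
  )
  profiles <- lapply(raw$profiles, function(p) {
    predictor_profile(sensitivity = unlist(p$sensitivity),
                      fpr = unlist(p$fpr),
                      severity_confusion = p$severity_confusion,
                      run_flip = p$run_flip, style = p$style)
  })
  bs <- raw$bootstrap
  run_config(cohort = cohort, profiles = profiles, n_runs = raw$n_runs,
             modes = unlist(raw$modes), strict = unlist(raw$strict),
             bootstrap = bootstrap_config(iterations = bs$iterations,
                                          side = bs$side, alpha = bs$alpha,
                                          m = bs$m, seed = bs$seed),
             schemes = unlist(raw$schemes), seed = raw$seed)
}

.log_stage <- function(stage, ...) {
  kv <- list(...)
  message(stage, ": ",
          paste(names(kv), unlist(kv), sep = "=", collapse = " "))
}

#' Simulate a full set of pipeline inputs to disk
#'
#' Generates the cohort, one prediction file per configured predictor
#' profile, and three-rater annotations; writes JSONL artifacts plus a
#' manifest carrying the seed, schema version and resolved config hash.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible named list of written file paths.
#' @export
pipeline_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  validate_cohort_spec(config$cohort)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)

  cohort <- generate_cohort(config$cohort)
  paths <- list(cases = file.path(out_dir, "cases.jsonl"))
  write_cases_jsonl(cohort, paths$cases)
  .log_stage("simulate", cases = nrow(cohort), hash = hash)

  for (nm in names(config$profiles)) {
    preds <- generate_predictions(cohort, config$profiles[[nm]],
                                  n_runs = config$n_runs,
                                  seed = config$seed + match(nm, names(config$profiles)),
                                  source = nm)
    p <- file.path(out_dir, paste0("predictions_", nm, ".jsonl"))
    write_predictions_jsonl(preds, p)
    paths[[paste0("predictions_", nm)]] <- p
    .log_stage("simulate", predictor = nm, rows = nrow(preds))
  }

  ann <- generate_rater_annotations(cohort, n_raters = 3,
                                    seed = config$seed + 100)
  paths$annotations <- file.path(out_dir, "annotations.jsonl")
  write_annotations_jsonl(ann, paths$annotations)

  paths$config <- file.path(out_dir, "config.yaml")
  write_run_config(config, paths$config)
  manifest <- list(schema_version = .SCHEMA_VERSION, seed = config$seed,
                   config_hash = hash, n_cases = nrow(cohort),
                   package_version = as.character(utils::packageVersion("periopeval")))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(paths)
}

#' Evaluate prediction files against a gold file
#'
#' @param config a [run_config()] (metric modes and strict settings).
#' @param gold_path cases JSONL path.
#' @param predictions_path predictions JSONL path.
#' @param out_csv output CSV path.
#' @return the metrics tibble, invisibly; written to `out_csv` with the
#'   config hash in a leading comment line.
#' @export
pipeline_evaluate <- function(config, gold_path, predictions_path, out_csv) {
  cohort <- read_cases_jsonl(gold_path)
  preds <- read_predictions_jsonl(predictions_path)
  res <- evaluate_predictions(cohort, preds, modes = config$modes,
                              strict = config$strict)
  .write_csv_hashed(res, out_csv, .config_hash(config))
  .log_stage("evaluate", rows = nrow(res))
  invisible(res)
}

#' Compare two strategies' prediction files
#'
#' One bootstrap paired test per metric x mode, reported in comparison-table
#' form (mean difference, 95% CI, raw and corrected p).
#'
#' @param config a [run_config()]; its bootstrap settings drive the tests.
#' @param gold_path cases JSONL path.
#' @param path_a,path_b predictions JSONL paths for strategies A and B
#'   (the test direction is B minus A).
#' @param out_csv output CSV path.
#' @param strict strict matching flag for the comparison.
#' @return tibble of comparison rows, invisibly.
#' @export
pipeline_compare <- function(config, gold_path, path_a, path_b, out_csv,
                             strict = FALSE) {
  cohort <- read_cases_jsonl(gold_path)
  runs_a <- read_predictions_jsonl(path_a)
  runs_b <- read_predictions_jsonl(path_b)
  rows <- list()
  for (md in config$modes) {
    for (metric in c("f1", "precision", "recall")) {
      bt <- bootstrap_paired_test(cohort, runs_a, runs_b, metric = metric,
                                  mode = md, strict = strict,
                                  config = config$bootstrap)
      rows[[length(rows) + 1]] <- dplyr::mutate(
        tidy(bt),
        comparison = paste0(unique(runs_a$source)[1], " vs ",
                            unique(runs_b$source)[1]),
        .before = 1
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  .write_csv_hashed(out, out_csv, .config_hash(config))
  .log_stage("compare", rows = nrow(out))
  invisible(out)
}

#' Stratified evaluation of a prediction file
#'
#' @param config a [run_config()]; `config$schemes` selects the analyses.
#' @param gold_path cases JSONL path.
#' @param predictions_path predictions JSONL path.
#' @param out_csv output CSV path.
#' @return tibble of per-stratum metric rows, invisibly.
#' @export
pipeline_stratify <- function(config, gold_path, predictions_path, out_csv) {
  if (length(config$schemes) == 0) {
    warning("no stratification schemes requested: nothing to do",
            call. = FALSE)
    return(invisible(tibble::tibble()))
  }
  cohort <- read_cases_jsonl(gold_path)
  preds <- read_predictions_jsonl(predictions_path)
  out <- list()
  for (sch in config$schemes) {
    assignments <- switch(
      sch,
      token_quartile = token_quartiles(cohort),
      complication_count = complication_strata(cohort),
      pdqi_quality = quality_strata(cohort),
      stop("unknown stratification scheme: ", sch, call. = FALSE)
    )
    res <- stratified_metrics(assignments, cohort, preds,
                              modes = config$modes, strict = FALSE)
    out[[sch]] <- res
    .log_stage("stratify", scheme = sch,
               strata = length(unique(assignments$stratum)))
  }
  out <- dplyr::bind_rows(out)
  .write_csv_hashed(out, out_csv, .config_hash(config))
  invisible(out)
}

.write_csv_hashed <- function(df, path, hash) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by the pipeline (skipping the hash comment)
#'
#' @param path CSV path.
#' @return tibble; the config hash is attached as attribute `config_hash`.
#' @export
read_pipeline_csv <- function(path) {
  first <- readLines(path, n = 1)
  out <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  attr(out, "config_hash") <- sub("^# config_hash=", "", first)
  out
}

#' Write a strategy run manifest as JSONL
#'
#' One line per (case, strategy, run) with parse status and predictor call
#' count, as produced by [run_strategy()].
#'
#' @param manifest manifest tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_manifest_jsonl <- function(manifest, path) {
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    c(list(schema_version = .SCHEMA_VERSION),
      as.list(manifest[i, , drop = FALSE]))
  })
  .write_jsonl(recs, path)
}
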