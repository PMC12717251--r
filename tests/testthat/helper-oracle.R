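# Independent brute-force metrics oracle: literal set enumeration over
# character vectors plus direct formula evaluation, sharing no code with the
# package's counting path.

oracle_case_sets <- function(gold, pred, strict) {
  key <- function(d) {
    if (nrow(d) == 0) return(character())
    lab <- tolower(gsub("\\s+", " ", trimws(d$label)))
    if (strict) {
      # most severe grade wins per label
      sev <- match(d$grade, c("unspecified", "mild", "moderate", "severe"))
      out <- character()
      for (lb in unique(lab)) {
        g <- d$grade[lab == lb][which.max(sev[lab == lb])]
        out <- c(out, paste0(lb, "::", g))
      }
      out
    } else {
      unique(lab)
    }
  }
  list(g = key(gold), p = key(pred))
}

oracle_counts <- function(gold, pred, strict) {
  s <- oracle_case_sets(gold, pred, strict)
  tp <- sum(s$p %in% s$g)
  c(tp = tp, fp = length(s$p) - tp, fn = length(s$g) - tp)
}

oracle_micro <- function(gold_list, pred_list, strict) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(gold_list)) {
    cc <- oracle_counts(gold_list[[i]], pred_list[[i]], strict)
    tp <- tp + cc[["tp"]]; fp <- fp + cc[["fp"]]; fn <- fn + cc[["fn"]]
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1)
}

oracle_macro <- function(gold_list, pred_list, strict) {
  precs <- recs <- f1s <- numeric(0)
  for (i in seq_along(gold_list)) {
    cc <- oracle_counts(gold_list[[i]], pred_list[[i]], strict)
    tp <- cc[["tp"]]; fp <- cc[["fp"]]; fn <- cc[["fn"]]
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    precs <- c(precs, prec); recs <- c(recs, rec); f1s <- c(f1s, f1)
  }
  c(precision = mean(precs), recall = mean(recs), f1 = mean(f1s))
}

# random small instance: up to max_cases cases over a small label alphabet,
# random gold and prediction sets with random grades
random_instance <- function(max_cases = 10, max_labels = 6) {
  labels <- paste0("cmp", seq_len(max_labels))
  grades <- c("mild", "moderate", "severe", "unspecified")
  n <- sample.int(max_cases, 1)
  draw_set <- function() {
    k <- sample(0:max_labels, 1)
    chosen <- sample(labels, k)
    diagnosis_set(chosen, sample(grades, k, replace = TRUE))
  }
  list(gold = replicate(n, draw_set(), simplify = FALSE),
       pred = replicate(n, draw_set(), simplify = FALSE))
}
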