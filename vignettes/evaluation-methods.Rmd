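---
title: "Evaluating multi-label complication detection: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-label complication detection: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(periopeval)
library(dplyr)
```

## The problem

Automatic detection of postoperative complications from clinical narratives
is a multi-label task: each surgical case carries a *set* of complication
diagnoses, each with a severity grade (mild / moderate / severe), and a
predictor — a language model, a rule system, or a human expert — returns
another set. periopeval implements the evaluation side of this problem: how
to score predicted sets against a consensus gold standard, how to compare
two prediction strategies statistically when every case has been inferred
several times, how to measure inter-rater agreement, and how to probe the
robustness of the results across document length, case complexity and
documentation quality.

Because real perioperative records are private, the package ships a
synthetic dual-center cohort generator whose defaults reproduce the
statistical structure such a study works with: per-center complication
prevalences, right-skewed document lengths, quality scores, a three-rater
annotation panel, and repeated stochastic predictor runs. Every analysis
function is exercised against this generator, so the full pipeline is
testable without any clinical data.

## The metric model

Each case $i$ is a pair of sets: gold $Y_i$ and prediction $\hat Y_i$.
Per-case counts are pure set arithmetic:

$$TP_i = |Y_i \cap \hat Y_i|, \qquad
  FP_i = |\hat Y_i - Y_i|, \qquad
  FN_i = |Y_i - \hat Y_i|.$$

**Micro averaging** pools counts over all $n$ cases first
($TP_{glob} = \sum_i TP_i$, etc.) and then computes precision, recall and
F1; a zero denominator yields 0.0. **Macro averaging** computes per-case
precision/recall/F1 with per-case zero-denominator rules and averages the
per-case scores. The per-case rules score a case with empty gold *and*
empty prediction — a trivially correct rejection — as F1 = 0. That is a
surprising convention: it penalizes predictors on exactly the cases they
got right, and in a cohort where roughly a third of cases have no
complication it depresses macro scores materially. We implement it exactly
as stated because it is the convention the reported numbers use, and expose
`macro_metrics(..., empty_empty = "one")` so the alternative scoring can be
compared in a sensitivity analysis. Which convention underlies any given
published macro figure generally cannot be verified from the outside; both
are one flag apart here.

```{r}
counts <- tibble::tibble(tp = c(1, 1, 0), fp = c(1, 0, 0), fn = c(1, 0, 0))
micro_metrics(counts)
macro_metrics(counts)              # empty-empty case scores 0
macro_metrics(counts, empty_empty = "one")
```

In **lenient** mode set elements are labels; in **strict** mode they are
(label, grade) pairs, so a correct label with the wrong severity counts as
both a false positive and a false negative. "Unspecified" matches only
"unspecified": no partial credit scheme is defined, and inventing one would
make strict scores incomparable. Strict metrics are therefore never above
lenient metrics, a property the test suite checks.

## Strategies: comprehensive vs targeted

The *comprehensive* strategy asks a predictor to assess all labels in one
call. The *targeted* strategy decomposes a case into one single-label call
per complication (22 calls for the default label set) and merges the
verdicts with two deterministic rules:

1. all-negative verdicts collapse to the sentinel
   `"no postoperative complications"` — represented internally as the empty
   diagnosis set;
2. a positive verdict for any configured *specific* infectious complication
   (default: pneumonia, the three surgical-site infection grades,
   bloodstream infection) suppresses "infection of unknown source", keeping
   the final output clinically coherent and non-redundant.

The subset in rule 2 is configuration, not a constant: the rule is
described by its purpose, and different criterion sets may enumerate the
specific infections differently.

A unit whose output cannot be parsed within the retry budget (default 2
retries) is recorded as a *negative verdict with a failure flag* rather
than an error: aggregation stays total and failures stay auditable in the
run manifests. The alternative — aborting the case — would silently bias
any comparison against the noisier backend.

The training-side counterpart, `expand_training_examples()`, turns an
$n$-case cohort into exactly $n \times L$ single-label examples
(146 × 22 = 3212 for the default setup):

```{r}
cohort <- generate_cohort(cohort_spec(n_patients = 146, seed = 7))
nrow(expand_training_examples(cohort))
```

## The synthetic cohort generator

`cohort_spec()` defaults describe the dual-center study conditions the
analysis assumes:

* **Label prevalences** are the observed per-center case proportions for 20
  named complications (counts over 146 and 102 cases). One table entry
  prints a percentage inconsistent with its count (17 of 102 cases given
  as 6.7%); we use count/n throughout. The full standardized framework has
  22 labels but only 20 are enumerated anywhere; the remaining two are
  configurable placeholders with zero prevalence, never guessed names.
* **Truth coherence.** Labels are sampled independently *except* that the
  rule-2 redundancy exclusion is applied to truth by default
  (`enforce_infection_exclusivity`): a consensus panel working under the
  non-redundancy principle would never record "infection of unknown
  source" alongside an identified specific infection. Without this the
  truth-echo equivalence between strategies would be violated by
  construction in ~3% of cases. Fully independent sampling remains
  available via the flag.
* **Severity grades** default to 0.5/0.3/0.2 over mild/moderate/severe for
  every graded label — a package choice (most complications mild, few
  severe); no severity distribution is published.
* **Token counts** are log-normal per center with means 6841.6 (center 1,
  concentrated: sdlog 0.35) and 8084.3 (center 2, broader: sdlog 0.55),
  matching the reported means and the relative-spread narrative. The
  tokenizer behind published token counts is unstated, so quartile
  *boundaries* are structural, not replicable; the default tokenizer
  (whitespace words, CJK characters counted individually) only needs to
  give a consistent ordering.
* **PDQI-9 scores** are normal(3.8, 0.5) clipped to the 1–5 scale.
* **Predictor profiles** are per-label sensitivity / false-positive rates
  plus a severity-confusion probability and a run-flip probability.
  Run-to-run variation redraws each per-label verdict with probability
  `run_flip` and otherwise keeps the base draw — the simplest mechanism
  that produces correlated repeated runs while leaving the marginal rates
  exactly equal in every run. The `ai_like` preset (sensitivity 0.85, fpr
  0.08) yields micro recall above precision under low-prevalence
  multi-label conditions; `human_like` (0.60, 0.015) the converse. These
  reproduce the qualitative signatures of machine vs expert behaviour, not
  any particular system's numbers.

What the generator does *not* emulate: real clinical prose (records are
schematic placeholders), label correlations beyond the infection rule
(only marginal prevalences are published; a dependence hook is documented
but off), center-specific severity case-mix, and annotator drift over
time. Passing tests therefore demonstrate that the *evaluation machinery*
is correct under controlled conditions — not that any model achieves a
particular score on real records.

## Statistical comparison

`bootstrap_paired_test()` implements the patient-level bootstrap paired
test: in each of B iterations (default 2000), patients are resampled with
replacement and *one* random inference run is drawn per strategy, so both
patient-level and inference-level variability enter the null distribution.
Micro metrics are recomputed on each resample by pooling the resampled
counts — the only reading consistent with "patient-level" resampling. The
p-value is the plain proportion of bootstrap differences on the null side
(no +1 smoothing), so p is always a multiple of 1/B; the 95% interval is
the percentile interval on the same differences (BCa would be an
alternative, not the default). The Bonferroni family size defaults to
m = 2 — the two sequential strategy comparisons that form one family — and
is configurable.

```{r}
cohort <- generate_cohort(cohort_spec(n_patients = 60, seed = 1))
weak  <- generate_predictions(cohort, predictor_profile(sensitivity = 0.6, fpr = 0.08),
                              n_runs = 5, seed = 2, source = "weak")
strong <- generate_predictions(cohort, predictor_profile(sensitivity = 0.85, fpr = 0.03),
                               n_runs = 5, seed = 3, source = "strong")
bt <- bootstrap_paired_test(cohort, weak, strong, metric = "f1",
                            config = bootstrap_config(iterations = 500, seed = 4))
tidy(bt)
```

For figure-style uncertainty (not hypothesis testing), `t_interval()`
gives the t-distribution interval across the R repeated runs.

The suite verifies two frequentist properties by simulation at reduced
scale (n = 100 cases, R = 5 runs, B = 500 iterations, 200 replicate
datasets — sizes chosen to keep the default run of the whole suite in the
minutes range while leaving Monte-Carlo error on a rejection-rate estimate
near 1.5 points): under a true null the one-sided rejection rate at
$\alpha = 0.05$ falls in [0.02, 0.10], and under two profiles whose
closed-form expected micro F1 differs by 0.15 (0.554 vs 0.706) the
rejection rate is at least 0.80.

## Agreement and consensus

`fleiss_kappa()` pools every (case, label) pair as one present/absent item
rated by all raters — "all complication categories combined" — and applies
the standard Fleiss formula; its confidence interval is a case-level
bootstrap percentile interval (2000 resamples), since no interval method is
named for the published κ. `consensus_gold()` admits a diagnosis when at
least 2 of 3 raters endorse the label; the grade is the majority grade
among endorsers, ties broken toward the more severe grade with an audit
flag — clinically conservative, and deterministic.

## Stratified sensitivity analyses

Three schemes partition the cohort (each disjoint and exhaustive; pooled
micro counts always equal the sum of per-stratum counts):

* `token_quartiles()` — empirical quartiles of token counts with stable
  tie-breaks (rank by count, ties in input order), pooled across centers by
  default;
* `complication_strata()` — gold-set size levels `<=1 / 2 / >=3`; the
  alternative `0 / 1 / >=2` grouping, described inconsistently for the same
  analysis, ships as a config preset with neither treated as ground truth;
* `quality_strata()` — PDQI-9 median split, with scores at the median
  assigned to "low" (deterministic and conservative; a tie rule is not
  published).

## Numerical and degenerate-input choices

* Label matching is case-insensitive exact matching after whitespace
  normalization — no fuzzy matching; near-miss names surface as
  unknown-label flags rather than being silently absorbed.
* Duplicate labels with conflicting grades keep the most severe grade and
  raise a warning flag.
* Zero-denominator metric values are exactly 0.0, per the printed edge
  rules, at both the global (micro) and per-case (macro) level.
* All-equal token counts or quality scores degrade to order-only /
  single-group splits with warnings, never errors.
* Time-shift anonymization draws one uniform integer offset in
  [−3650, 3650] days per patient; only "randomly generated" is specified,
  and intervals are preserved under any constant offset. Identifier
  removal operates on structured fields only; free-text de-identification
  is out of scope.
* Every generator accepts a seed and is exactly reproducible; seeds are
  plain integers below 2³¹.

## Limitations

The package evaluates predictions; it contains no language model and does
not reproduce any published real-data score. Conclusions from synthetic
runs transfer to real data only to the extent that the generator's
structural assumptions (independent labels, stable per-label error rates,
exchangeable runs) hold there. Macro-averaged results are sensitive to the
empty-empty convention discussed above; comparisons between published
numbers computed under different conventions are not meaningful to the
third decimal.
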