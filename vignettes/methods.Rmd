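---
title: "Multi-modal clinical-text risk models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal clinical-text risk models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskfuse)
```

## The problem and the design

`riskfuse` models a patient-level binary outcome from free-text clinical
notes in a *matched case-control* design. Each case is paired with `k`
controls (default 5) who share the case's baseline risk percentile (an
integer 1–100 from a structured-data risk model, 1 = riskiest) and
facility, and who inherit the case's index date so both arms contribute
notes from equivalent follow-up windows. Patients are stratified into risk
tiers by fixed percentile cut points — high = 1, moderate = 2–24,
low = 25–100 — and every model is fit within a tier.

Because controls are matched on the baseline score, the baseline score
itself carries no discriminative information inside the cohort: a
classifier given only the percentile must score AUC 0.50. That is not an
assumption but a testable calibration property, and the test suite and
acceptance script verify it on synthetic cohorts. Conversely, any AUC
above 0.50 from note text measures discrimination *beyond* the baseline
model.

Notes are restricted to a window of 5–30 whole days before the index
date. Notes within 0–4 days of the index are removed because
documentation that close to a case's death date can be contaminated by
post-mortem entries; the day-5 boundary note is retained (the retained
interval is closed, `[5, 30]`). Day arithmetic uses calendar dates only.

## Featurization

**Open vocabulary (count).** Text is lowercased, split on runs of
non-alphanumeric characters (apostrophes separate; digits are retained
because clinical notes carry meaningful numerics; acronyms such as "SI"
stay as tokens), stopworded with a standard English function-word list,
and expanded to unigrams plus adjacent bigrams formed *after* stopword
removal (so "alcohol and suicide" contributes the bigram "alcohol
suicide"). A term enters the vocabulary iff its document frequency `df`
satisfies `min_df <= df <= floor(max_df * n_docs)` — presence, not
multiplicity. The defaults (`min_df = 100`, `max_df = 0.9`) suit corpora
of tens of thousands of notes; desk-scale examples lower `min_df`. The
vocabulary is fit on the *training partition only* and applied frozen to
validation and test, preventing vocabulary-selection leakage. A TF-IDF
variant (`idf(t) = ln((1+n)/(1+df)) + 1`, rows L2-normalized) is available
but off by default; raw counts classify marginally better in this setting.

**Closed vocabulary (semantic).** Each lexicon category (a named set of
lowercase unigram terms with a polarity tag) scores a note as the
proportion of its stopword-removed tokens matching the category. Each
category may additionally emit `_neg_k` variants in which a match is
suppressed when a negation cue (`no, not, never, denies, denied, without,
n't`) occurs within the `k` tokens immediately preceding the match.
Negation lookback scans the *raw, pre-stopword* sequence: common cues are
themselves stopwords, and removing them before lookback would silently
disable negation control. Scores are proportions in [0, 1]; polarity is
metadata for reporting, not a sign flip. Multiword dictionary entries are
out of scope.

## Fusion and the α/β weighting

Count and semantic matrices are merged by note id into a joint matrix
whose columns carry a feature-set tag. Count features keep selection
weight 1; each semantic feature gets `w = (n_count / n_semantic) * α`.
These are relative sampling propensities passed to the learner
(`xgb.DMatrix(feature_weights=)`); the learner normalizes internally, so
the weights are deliberately not normalized to sum to one. They only
matter when column subsampling is active, hence `colsample_bynode < 1` in
the defaults. The reporting axis is `β = α/(α+1)`, the probability that a
candidate drawn from the two balanced sets is semantic. The default grid
spans `β` from 0.01 to 0.83. α applies uniformly to all semantic columns;
per-lexicon weighting is not modelled.

A note on printing: `β(0.60) = 0.375`, and base R's `round()` (half to
even, on binary doubles) prints it as 0.37. Published β tables use
conventional half-up rounding, so the package provides `round_half_up()`
and uses it wherever a β table is printed.

## Model fitting and selection

The learner is XGBoost (binary logistic objective) on note-level rows —
training on notes rather than patients greatly enlarges the sample — with
missing values retained and no normalization, as tree ensembles handle
both natively. Class imbalance from 1:k matching is absorbed by
`scale_pos_weight = n_control/n_case` (configurable off). Training is
single-threaded with a fixed seed in tests, making every fit bit-for-bit
reproducible; parallel training is possible but not deterministic.

Patients are split 64/16/20 into train/validation/test; all of a
patient's notes inherit its partition. `grouped_split(group=)` can instead
allocate whole *match groups* to one partition. This matters for the null
calibration check at desk scale: with only one or two matched sets per
percentile value, patient-level splitting puts a set's case and controls
into different partitions, making train and test case rates anticorrelated
conditional on the percentile, and a percentile-only model then scores
visibly *below* 0.5 — an artifact of per-set leave-out, not of the
matching. At realistic scale (thousands of sets, many per percentile) the
artifact is negligible, which is why the package's null-matching check
allocates matched sets jointly and recovers AUC 0.50 exactly.

Hyperparameter search reconciles two selection mechanisms: a randomized
search (default 100 draws from depth 2–10, learning rate log-uniform
0.01–0.3, 50–500 trees, subsample and per-node column-sample 0.5–1,
minimum child weight 1–10) is coarsely ranked by patient-grouped 5-fold
cross-validation on the training partition, then the top `top_k`
configurations are refit on the full training partition and the final
model is the one with the best *patient-level AUC on the withheld
validation partition*. The validation set therefore genuinely selects
among several finalists rather than rubber-stamping the CV winner. For the
joint mode this whole procedure runs once per α in the grid and the α with
the best validation patient-level AUC wins; its β is reported.

## Evaluation

Note probabilities are averaged per patient; the patient-level AUC is the
Wilcoxon–Mann–Whitney concordance (ties count 1/2), which the tests verify
equals trapezoidal ROC integration to 1e-12. Confidence intervals come
from a nonparametric bootstrap (default 1000 replicates) resampling
*patients*, stratified by case/control so every replicate contains both
classes — the patient is the outcome's unit of analysis, so it is the
resampling unit. Two models are called significantly different only if
their intervals are disjoint; no DeLong or permutation test is attempted.
The thresholded battery (Brier, accuracy, precision, recall, specificity,
PPV, NPV, F1) uses a fixed 0.5 cutoff; on imbalanced patient-level scores
this regularly produces zero predicted positives, in which case the
undefined ratios are reported as 0 with an explicit degeneracy flag rather
than NA, matching how such cells are conventionally tabulated.

## The synthetic-data generator

The generator emulates the study conditions the pipeline targets, not the
language of real notes:

- **Matched structure.** `n_cases` cases each with `controls_per_case`
  (default 5) controls sharing percentile, facility and index date. Tier
  mix defaults to 14% high / 50% moderate / 36% low, the composition of
  the motivating cohort.
- **Note counts.** Negative-binomial per patient, moment-matched to
  tier-and-status means/SDs (defaults: high 37.9 (53.9) cases vs 40.0
  (82.3) controls; moderate 15.0 (32.7) vs 12.2 (40.9); low 9.1 (18.5) vs
  7.0 (19.0)), truncated at one note. The SDs far exceed the means, ruling
  out Poisson counts. Truncation lifts the realized mean by exactly
  P(X = 0), which the tests account for.
- **Dates.** Uniform over the 5–30-day window, plus decoy notes in the
  0–4 and 31–60-day ranges so the window filter has work to do.
- **Text.** Background tokens drawn from a Zipf rank-frequency
  distribution (exponent 1.1) over a tier-dependent vocabulary (defaults
  2500/1800/1000 — lower-tier patients receive less care and show smaller
  vocabularies; sizes are desk-scale choices), ~60 tokens per note.
- **Signal.** `signal_mode = "semantic"` oversamples the built-in
  lexicon's 120-term "distress" category in case notes by `effect_size`
  (default 3); because the mass spreads over many terms, each term stays
  individually rare and falls below realistic `min_df` thresholds — the
  regime where aggregation by a dictionary beats counting.
  `signal_mode = "count"` plants the same mass in 25 reserved tokens
  absent from every lexicon, the regime where counting wins and semantic
  models sit at chance. Signal is a frequency multiplier, never an
  exclusive token, so classification stays nontrivial.

What passing tests on generated corpora do *not* show: anything about real
clinical language (templated notes, misspellings, PHI, acronym ambiguity,
section structure) or about the transportability of any particular
lexicon. They validate the pipeline's mechanics — leakage-free splitting,
correct featurization, the weighting's steering effect, calibration of the
null — under controlled truth.

## Numerical choices and degenerate inputs

- `max_df` is strict ("more than 90% of documents"): `df ≤ floor(0.9 n)`
  survives. Vocabulary order is lexicographic (byte order) for
  reproducibility.
- Empty documents tokenize to empty streams, score 0 on every category,
  and produce all-zero count rows; they are valid inputs everywhere.
- A vocabulary filtered to nothing is a warning, not an error.
- SMD uses the pooled-SD form `|m1 - m0| / sqrt((v1 + v0)/2)`; binary
  covariates use proportions with variance `p(1-p)`. Zero pooled SD with
  equal means is 0; with unequal means it is reported infinite with a
  warning.
- Matching is greedy in seeded-random case order, without control reuse;
  cases short of `k` eligible controls keep what was found and are
  flagged. The percentile must match exactly, and facility must match
  when a facility column exists.
- Bootstrap replicates that are degenerate (all-tied scores) contribute
  their defined AUC of 0.5; nothing is resampled away.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
synthetic cohorts of 60–200 cases (up to 1200 patients, a few thousand
notes), vocabularies of a few hundred surviving terms, searches of 2–4
configurations, and 200–1000 bootstrap replicates. These sizes are stated
here as the package's own validation conditions; the pipeline itself has
no size-dependent logic and the defaults (`min_df = 100`, 100 search
iterations, 1000 replicates) target realistically sized corpora.

## Known limitations

- Semantic scoring is unigram-only; multiword lexicon entries are not
  supported.
- The negation rule is a fixed-window lookback; scope-aware negation
  (e.g. dependency-based) is out of scope.
- Probabilities are not calibrated; only ranking metrics should be
  interpreted.
- Alternative learners (regularized logistic regression, random forests,
  neural models) are deliberately not wrapped; the weighting scheme is
  specific to learners with per-feature candidate-sampling weights.
- CI-overlap significance is conservative; adjacent models with
  overlapping intervals may still differ.
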