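# riskfuse

Tier-stratified, multi-modal text classification for clinical risk
prediction, with a synthetic matched-cohort generator for end-to-end
validation.

`riskfuse` is aimed at clinical-informatics researchers who want to predict
a patient-level outcome (the motivating application is suicide risk among
patients already scored by a structured-data model) from free-text clinical
notes, in a matched case-control design stratified by baseline risk tier.
It combines two NLP featurizations of each note:

- **open-vocabulary ("count") features** — unigram/bigram token counts over
  the corpus vocabulary, filtered by document frequency (`min_df`,
  `max_df`), and
- **closed-vocabulary ("semantic") features** — proportions of note tokens
  matching lexicon categories, optionally negation-controlled (a
  `_neg_k` variant suppresses matches preceded within `k` tokens by a
  negation cue),

and fuses them in a single gradient-boosted tree classifier whose
*per-feature selection weights* rebalance the two feature sets.

## The weighting scheme

A joint matrix has far more count columns than semantic columns
(`n_count >> n_semantic`), so uniform column sampling would almost never
offer a semantic feature at a tree split. Count features keep weight 1 and
every semantic feature gets

    w = (n_count / n_semantic) * alpha

so `alpha` controls the *relative* selection probability of the semantic
set. Results are reported on the axis

    beta = alpha / (alpha + 1)

the probability that a split candidate drawn from the two balanced sets is
semantic: `beta = 0.5` means the two feature sets are offered equally
often. The default grid `alpha ∈ {0.01, 0.03, 0.06, 0.10, 0.30, 0.60,
1.00, 2.50, 5.00}` corresponds to `beta ∈ {0.01, 0.03, 0.06, 0.09, 0.23,
0.38, 0.50, 0.71, 0.83}`.

Models are trained on note-level rows (a note's label is its patient's
case/control status), partitioned 64/16/20 into train/validation/test *by
patient* so no patient's notes leak across partitions. Hyperparameters are
chosen by randomized search with patient-grouped cross-validation, the
winner selected by patient-level AUC on the validation partition. A
patient's score is the mean of their note probabilities; discrimination is
summarized by the patient-level concordance AUC with a stratified
1000-replicate bootstrap interval. Because controls are matched to cases
on the baseline risk percentile, AUC > 0.50 measures discrimination *over
and above* the baseline score, not over chance.

## Worked example

Real data of this kind is access-restricted, so the package ships a
generator for synthetic matched corpora with plantable signal. Planting
signal in idiosyncratic tokens (invisible to any lexicon) should favour the
count and joint models while the semantic model stays near chance — and it
does:

```r
library(riskfuse)

spec <- generator_spec(n_cases = 60, controls_per_case = 3,
                       tier_mix = c(high = 0, moderate = 1, low = 0),
                       signal_mode = "count", effect_size = 4, seed = 7)
corpus <- generate_corpus(spec)

cfg <- default_config()
cfg$features$min_df <- 50L                  # desk-scale corpus
cfg$fusion$alpha_grid <- c(0.03, 0.60, 5.00)
cfg$search <- list(n_iterations = 4L, cv_folds = 3L, top_k = 2L, seed = 7L)

experiment <- run_experiment(corpus$cohort, corpus$notes, corpus$lexicon,
                             config = cfg)
experiment
#> Tier-stratified model comparison (patient-level AUC [95% CI])
#>   moderate  semantic 0.56 [0.38-0.74] | count 0.85 [0.67-0.98] | joint 0.84 [0.66-0.98] (beta 0.03)
```

The count model recovers the planted signal (AUC 0.85), the semantic model
cannot see it (0.56, interval spanning 0.5), and the joint sweep selects a
count-dominant weighting (beta 0.03). The weighting itself, at the
motivating study's feature tallies:

```r
compute_weights(n_count = 11018, n_semantic = 516, alpha = 0.03)
#> <weighting_scheme> alpha=0.03 beta=0.029 | 11018 count @ w=1, 516 semantic @ w=0.6406
```

`write_report(experiment, "results/")` exports `report.json` /
`report.csv` with AUCs, bootstrap intervals and the full metric battery
(Brier, accuracy, precision, recall, specificity, PPV, NPV, F1) at the
document and patient level. A command-line front end for simulation and
the full experiment lives at `inst/cli/riskfuse.R`.

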