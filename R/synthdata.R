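#' Synthetic-corpus generator specification
#'
#' Defines the study conditions a generated corpus emulates: matched
#' case-control groups sharing a risk percentile and facility, tier- and
#' status-dependent note counts (defaults follow the descriptive document
#' counts of the motivating cohort: high-tier cases average ~38 notes with
#' SD well above the mean, low-tier cases ~9), a Zipf-distributed background
#' vocabulary whose size shrinks with tier (lower-tier patients see less
#' care and have smaller vocabularies), and plantable case-associated
#' signal, either in lexicon terms (semantic signal, spread thinly over many
#' individually-rare terms) or in reserved idiosyncratic tokens (count
#' signal).
#'
#' @param n_cases number of cases.
#' @param controls_per_case matched controls per case (default 5).
#' @param tier_mix named proportions over high/moderate/low; defaults mirror
#'   the motivating cohort's tier composition.
#' @param note_count_params data.frame (tier, status, mean, sd) of notes per
#'   patient; defaults to the motivating cohort's document-count table.
#' @param vocab_size named per-tier background vocabulary size (desk-scale
#'   defaults).
#' @param tokens_per_note mean note length in tokens.
#' @param signal_mode `"none"`, `"semantic"`, `"count"`, or `"mixed"`.
#' @param effect_size relative frequency multiplier (>= 1) for signal
#'   tokens in case notes.
#' @param signal_mass total probability mass of the signal token set in
#'   control notes (multiplied by `effect_size` in case notes).
#' @param zipf_exponent background token rank-frequency exponent.
#' @param decoy_rate expected decoy notes (outside the 5-30-day window) per
#'   patient, exercising the window filter.
#' @param seed integer seed; generation is fully reproducible under it.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_cases = 100L,
                           controls_per_case = 5L,
                           tier_mix = c(high = 0.14, moderate = 0.50,
                                        low = 0.36),
                           note_count_params = default_note_counts(),
                           vocab_size = c(high = 2500L, moderate = 1800L,
                                          low = 1000L),
                           tokens_per_note = 60L,
                           signal_mode = "none",
                           effect_size = 3,
                           signal_mass = 0.02,
                           zipf_exponent = 1.1,
                           decoy_rate = 0.3,
                           seed = 1L) {
  stopifnot(abs(sum(tier_mix) - 1) < 1e-8, effect_size >= 1,
            controls_per_case >= 1L,
            signal_mode %in% c("none", "semantic", "count", "mixed"),
            all(c("high", "moderate", "low") %in% names(tier_mix)))
  structure(as.list(environment()), class = "generator_spec")
}

#' Default notes-per-patient distribution parameters
#'
#' Mean/SD of notes per patient by tier and case status. SDs far exceed
#' means, which is why counts are drawn negative-binomially rather than
#' Poisson.
#'
#' @return data.frame with columns tier, status, mean, sd.
#' @export
default_note_counts <- function() {
  data.frame(
    tier = rep(c("high", "moderate", "low"), each = 2L),
    status = rep(c("case", "control"), 3L),
    mean = c(37.9, 40.0, 15.0, 12.2, 9.1, 7.0),
    sd = c(53.9, 82.3, 32.7, 40.9, 18.5, 19.0),
    stringsAsFactors = FALSE
  )
}

#' Built-in synthetic lexicon
#'
#' A small dictionary in the closed-vocabulary format: a "distress"
#' category whose many individually-rare terms aggregate the planted
#' semantic signal, and a smaller neutral "support" category. Both emit a
#' 3-token negation variant. Terms are synthetic tokens, not clinical
#' vocabulary.
#'
#' @param n_signal_terms terms in the signal-bearing category.
#' @param n_neutral_terms terms in the neutral category.
#' @return a `lexicon` named `synlex`.
#' @export
synthetic_lexicon <- function(n_signal_terms = 120L, n_neutral_terms = 40L) {
  lexicon("synlex", list(
    distress = list(terms = sprintf("dstr%03d", seq_len(n_signal_terms)),
                    polarity = "negative", negation_variants = 3L),
    support = list(terms = sprintf("supp%03d", seq_len(n_neutral_terms)),
                   polarity = "positive", negation_variants = 3L)
  ))
}

#' Generate a matched case-control cohort
#'
#' Each case receives `controls_per_case` controls sharing its exact risk
#' percentile, facility and index date (so matched follow-up windows are
#' identical by construction). Percentiles are tier-appropriate: high = 1,
#' moderate uniform on 2-24, low uniform on 25-100. Index dates spread over
#' a two-year span. Two structured covariates (age, female) are attached
#' for balance diagnostics.
#'
#' @param spec a [generator_spec()].
#' @return cohort data.frame (the same shape [read_cohort()] returns).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_cases
  tiers <- sample(names(spec$tier_mix), n, replace = TRUE,
                  prob = spec$tier_mix)
  pct <- vapply(tiers, function(t) switch(t, high = 1L,
                                          moderate = sample(2:24, 1L),
                                          low = sample(25:100, 1L)), 1L)
  k <- spec$controls_per_case
  facility <- sample(sprintf("fac%02d", 1:6), n, replace = TRUE)
  index_date <- as.Date("2017-01-01") + sample(0:729, n, replace = TRUE)
  per_group <- k + 1L
  total <- n * per_group
  grp <- rep(seq_len(n), each = per_group)
  cohort <- data.frame(
    patient_id = sprintf("p%06d", seq_len(total)),
    status = rep(c("case", rep("control", k)), n),
    index_date = index_date[grp],
    percentile = pct[grp],
    facility = facility[grp],
    match_group = sprintf("mg%05d", grp),
    age = pmax(18L, round(stats::rnorm(total, 60, 16))),
    female = stats::rbinom(total, 1L, 0.07),
    stringsAsFactors = FALSE
  )
  cohort$tier <- assign_tier(cohort$percentile)
  cohort
}

nbinom_counts <- function(n, mean, sd) {
  v <- sd^2
  x <- if (v > mean) {
    stats::rnbinom(n, size = mean^2 / (v - mean), mu = mean)
  } else {
    stats::rpois(n, mean)
  }
  pmax(1L, x)  # every patient contributes at least one note
}

#' Generate synthetic clinical notes for a cohort
#'
#' Per-patient note counts are negative-binomial, moment-matched to the
#' tier/status mean and SD and truncated at 1. Note dates fall uniformly
#' 5-30 days before the index date, plus decoy notes in the 0-4 and
#' 31-60-day ranges so window filtering is consequential. Note text is a
#' bag of background tokens drawn from a Zipf rank-frequency distribution
#' over the tier's vocabulary, mixed with signal tokens: lexicon "distress"
#' terms for semantic signal, reserved idiosyncratic tokens for count
#' signal, their total mass multiplied by `effect_size` in case notes.
#' Signal is planted by frequency multiplication, not exclusive tokens, so
#' classification stays nontrivial at moderate effect sizes.
#'
#' @param cohort cohort from [generate_cohort()].
#' @param spec the same [generator_spec()].
#' @param lexicon_ the lexicon supplying semantic signal terms
#'   ([synthetic_lexicon()] by default).
#' @return list with `notes` (data.frame) and `truth` (planted-signal
#'   record: mode, tokens, category, effect_size).
#' @export
generate_notes <- function(cohort, spec, lexicon_ = synthetic_lexicon()) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 1L)
  ncp <- spec$note_count_params
  sem_tokens <- lexicon_$categories$distress$terms
  cnt_tokens <- sprintf("idio%03d", 1:25)
  sig_tokens <- switch(spec$signal_mode,
                       none = character(0),
                       semantic = sem_tokens,
                       count = cnt_tokens,
                       mixed = c(sem_tokens, cnt_tokens))
  # Zipf background distributions, one per tier
  zipf <- lapply(spec$vocab_size, function(V) {
    p <- 1 / seq_len(V)^spec$zipf_exponent
    p / sum(p)
  })
  supp <- lexicon_$categories$support$terms
  p_supp <- 0.01  # neutral lexicon terms, status-independent
  pid <- character(0); day <- integer(0); text <- character(0)
  for (i in seq_len(nrow(cohort))) {
    tier <- as.character(cohort$tier[i])
    status <- cohort$status[i]
    par <- ncp[ncp$tier == tier & ncp$status == status, ]
    n_notes <- nbinom_counts(1L, par$mean, par$sd)
    n_decoy <- stats::rpois(1L, spec$decoy_rate)
    days <- c(sample(5:30, n_notes, replace = TRUE),
              sample(c(0:4, 31:60), n_decoy, replace = TRUE))
    V <- spec$vocab_size[[tier]]
    p_sig <- spec$signal_mass *
      (if (status == "case") spec$effect_size else 1)
    p_sig <- min(p_sig, 0.5)
    if (length(sig_tokens) == 0L) p_sig <- 0
    texts <- vapply(days, function(d) {
      len <- max(5L, stats::rpois(1L, spec$tokens_per_note))
      kind <- sample.int(3L, len, replace = TRUE,
                         prob = c(1 - p_sig - p_supp, p_sig, p_supp))
      toks <- character(len)
      bg <- kind == 1L
      toks[bg] <- sprintf("w%05d", sample.int(V, sum(bg), replace = TRUE,
                                              prob = zipf[[tier]]))
      if (any(kind == 2L)) {
        toks[kind == 2L] <- sample(sig_tokens, sum(kind == 2L),
                                   replace = TRUE)
      }
      if (any(kind == 3L)) {
        toks[kind == 3L] <- sample(supp, sum(kind == 3L), replace = TRUE)
      }
      paste(toks, collapse = " ")
    }, "")
    pid <- c(pid, rep(cohort$patient_id[i], length(days)))
    day <- c(day, days)
    text <- c(text, texts)
  }
  idx <- as.Date(cohort$index_date)[match(pid, cohort$patient_id)]
  notes <- data.frame(
    note_id = sprintf("n%07d", seq_along(pid)),
    patient_id = pid,
    note_date = idx - day,
    text = text,
    stringsAsFactors = FALSE
  )
  list(notes = notes,
       truth = list(mode = spec$signal_mode, tokens = sig_tokens,
                    category = if (spec$signal_mode %in%
                                   c("semantic", "mixed"))
                      "synlex.distress" else NULL,
                    effect_size = spec$effect_size))
}

#' Generate a complete synthetic corpus
#'
#' Convenience wrapper: cohort + notes + lexicon + truth record under one
#' seed.
#'
#' @param spec a [generator_spec()].
#' @return object of class `synthetic_corpus`: list with `cohort`, `notes`,
#'   `lexicon`, `truth`, `spec`.
#' @export
generate_corpus <- function(spec) {
  lex <- synthetic_lexicon()
  cohort <- generate_cohort(spec)
  gen <- generate_notes(cohort, spec, lexicon_ = lex)
  structure(list(cohort = cohort, notes = gen$notes, lexicon = lex,
                 truth = gen$truth, spec = spec),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d patients (%d cases), %d notes, signal=%s\n",
              nrow(x$cohort), sum(x$cohort$status == "case"),
              nrow(x$notes), x$truth$mode))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits the cohort CSV and notes JSONL in the formats the cohort loaders
#' consume, the lexicon as TSV, the planted-signal truth record and a
#' manifest echoing every generation parameter.
#'
#' @param corpus a `synthetic_corpus`.
#' @param dir output directory (created if absent).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(corpus$cohort, file.path(dir, "cohort.csv"))
  write_notes(corpus$notes, file.path(dir, "notes.jsonl"))
  write_lexicon(corpus$lexicon, file.path(dir, "lexicon.tsv"))
  jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  manifest <- corpus$spec
  manifest$note_count_params <- NULL
  jsonlite::write_json(c(manifest,
                         list(note_count_params = corpus$spec$note_count_params)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a lexicon to the TSV interchange format
#'
#' Inverse of [load_lexicon()] for the TSV layout.
#'
#' @param lex a `lexicon`.
#' @param path output path.
#' @export
write_lexicon <- function(lex, path) {
  df <- data.frame(
    lexicon = lex$name,
    category_id = names(lex$categories),
    polarity = vapply(lex$categories, `[[`, "", "polarity"),
    negation_variants = vapply(lex$categories, function(c)
      paste(c$negation_variants, collapse = ","), ""),
    terms = vapply(lex$categories, function(c)
      paste(c$terms, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
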