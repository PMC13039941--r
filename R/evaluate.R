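#' Aggregate note-level probabilities to patients
#'
#' A patient's score is the arithmetic mean of their notes' predicted
#' probabilities; the class outcome lives at the patient level, so all
#' discrimination metrics are computed on these means. Cohort patients with
#' no scored note are omitted with a warning.
#'
#' @param note_probs numeric vector of note-level probabilities.
#' @param note_patients patient id per note.
#' @param cohort cohort data.frame carrying `patient_id` and `status`.
#' @return data.frame with `patient_id`, `probability`, `n_notes`, `status`.
#' @export
aggregate_patients <- function(note_probs, note_patients, cohort) {
  stopifnot(length(note_probs) == length(note_patients))
  unknown <- setdiff(note_patients, cohort$patient_id)
  if (length(unknown)) stop("scored notes reference unknown patient(s): ",
                            paste(utils::head(unknown, 5L), collapse = ", "))
  agg <- stats::aggregate(list(probability = note_probs),
                          by = list(patient_id = note_patients), FUN = mean)
  agg$n_notes <- as.integer(table(note_patients)[agg$patient_id])
  agg$status <- cohort$status[match(agg$patient_id, cohort$patient_id)]
  unscored <- setdiff(cohort$patient_id, agg$patient_id)
  if (length(unscored)) {
    warning(length(unscored), " cohort patient(s) had no scored note; omitted")
  }
  agg
}

#' Area under the ROC curve by pairwise concordance
#'
#' The Wilcoxon-Mann-Whitney estimator: over all case-control pairs, the
#' fraction of pairs where the case scores higher, counting ties as 1/2.
#' Identical to trapezoidal integration of the empirical ROC curve.
#'
#' @param probs numeric scores.
#' @param labels `"case"`/`"control"`, logical, or 0/1 (case = 1).
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.8, 0.4, 0.6, 0.3, 0.1), c(1, 1, 0, 0, 0))
#' @export
roc_auc <- function(probs, labels) {
  y <- as_label01(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC needs at least one case and one control")
  r <- rank(probs)  # midranks handle ties as 1/2 wins
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap percentile confidence interval for the patient-level AUC
#'
#' Patients are resampled with replacement, stratified by case/control so
#' every replicate contains both classes, and the AUC is recomputed per
#' replicate; the 2.5th and 97.5th percentiles (for `level` = 0.95) bound
#' the interval.
#'
#' @param probs patient-level scores.
#' @param labels patient-level labels.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(probs, labels, n_boot = 1000L, level = 0.95,
                         seed = 1L) {
  y <- as_label01(labels)
  stopifnot(n_boot >= 1L, sum(y == 1) >= 2L, sum(y == 0) >= 2L)
  i1 <- which(y == 1); i0 <- which(y == 0)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    s1 <- sample(i1, length(i1), replace = TRUE)
    s0 <- sample(i0, length(i0), replace = TRUE)
    roc_auc(c(probs[s1], probs[s0]),
            c(rep(1L, length(s1)), rep(0L, length(s0))))
  }, 0)
  q <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  c(ci_low = q[1], ci_high = q[2])
}

#' Compare two models by confidence-interval overlap
#'
#' Two models are called significantly different iff their bootstrap
#' confidence intervals are disjoint. This is a conservative screen, not a
#' formal test of AUC difference.
#'
#' @param report_a,report_b `evaluation_report`s, or numeric `c(low, high)`
#'   intervals.
#' @return `"significant"` or `"not_significant"`.
#' @export
significance_by_overlap <- function(report_a, report_b) {
  ci <- function(r) {
    if (inherits(r, "evaluation_report")) c(r$ci_low, r$ci_high) else
      as.numeric(r)[1:2]
  }
  a <- ci(report_a); b <- ci(report_b)
  if (a[2] < b[1] || b[2] < a[1]) "significant" else "not_significant"
}

#' Thresholded classification metric battery
#'
#' Brier score plus the confusion-matrix battery (accuracy, precision,
#' recall, specificity, PPV, NPV, F1) at a fixed decision cutoff. Ratios
#' with an empty denominator (e.g. precision with no predicted positives)
#' are reported as 0 and flagged in `degenerate`.
#'
#' @param probs scores in \[0, 1\].
#' @param labels case/control labels.
#' @param threshold decision cutoff in (0, 1); default 0.5.
#' @return named list of metrics plus `degenerate`, a character vector of
#'   metric names whose denominator was empty.
#' @export
metric_battery <- function(probs, labels, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  y <- as_label01(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  degenerate <- character(0)
  ratio <- function(num, den, nm) {
    if (den == 0) { degenerate <<- c(degenerate, nm); 0 } else num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  specificity <- ratio(tn, tn + fp, "specificity")
  npv <- ratio(tn, tn + fn, "npv")
  f1 <- if (precision + recall == 0) {
    degenerate <- c(degenerate, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  list(brier = mean((probs - y)^2),
       accuracy = (tp + tn) / length(y),
       precision = precision, recall = recall,
       specificity = specificity, ppv = precision, npv = npv, f1 = f1,
       threshold = threshold, degenerate = unique(degenerate))
}

#' Full evaluation report at one level
#'
#' Bundles AUC, its bootstrap interval, and the metric battery for one set
#' of scores (document-level note probabilities or patient-level means).
#'
#' @param probs scores.
#' @param labels labels.
#' @param level `"document"` or `"patient"`.
#' @param n_boot bootstrap replicates.
#' @param threshold cutoff for the battery.
#' @param seed bootstrap seed.
#' @return object of class `evaluation_report`.
#' @export
evaluation_report <- function(probs, labels, level = "patient",
                              n_boot = 1000L, threshold = 0.5, seed = 1L) {
  stopifnot(level %in% c("document", "patient"))
  auc <- roc_auc(probs, labels)
  ci <- bootstrap_ci(probs, labels, n_boot = n_boot, seed = seed)
  structure(list(level = level, auc = auc,
                 ci_low = ci[[1]], ci_high = ci[[2]], n_boot = n_boot,
                 metrics = metric_battery(probs, labels, threshold),
                 threshold = threshold, n = length(probs)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<%s-level evaluation> AUC %.3f [%.3f-%.3f] (n=%d, %d boot)\n",
              x$level, x$auc, x$ci_low, x$ci_high, x$n, x$n_boot))
  m <- x$metrics
  cat(sprintf("  brier %.4f  acc %.4f  prec %.4f  rec %.4f  spec %.4f  f1 %.4f\n",
              m$brier, m$accuracy, m$precision, m$recall, m$specificity,
              m$f1))
  if (length(m$degenerate)) {
    cat("  degenerate (empty denominator):",
        paste(m$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}
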