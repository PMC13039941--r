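#' Default experiment configuration
#'
#' All knobs of the end-to-end tier-stratified experiment with their
#' defaults: the 5-30-day pre-index note window, document-frequency filter
#' thresholds (min_df 100 / max_df 0.9; lower min_df for small corpora),
#' the nine-value alpha grid, the 64/16/20 patient-grouped split, the
#' randomized hyperparameter search, and the bootstrap evaluation.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    window = list(min_days = 5L, max_days = 30L),
    features = list(min_df = 100L, max_df = 0.9, ngram_orders = c(1L, 2L),
                    weighting = "count"),
    fusion = list(alpha_grid = default_alpha_grid()),
    split = list(fractions = c(train = 0.64, validation = 0.16,
                               test = 0.20), seed = 1L),
    search = list(n_iterations = 10L, cv_folds = 5L, top_k = 3L, seed = 1L),
    model = list(class_weighting = TRUE),
    evaluate = list(n_boot = 1000L, threshold = 0.5, seed = 1L),
    feature_mode = c("semantic", "count", "joint")
  )
}

#' Load an experiment configuration from YAML
#'
#' Keys present in the file override the [default_config()] values;
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  if (!is.null(user$split$fractions)) {
    cfg$split$fractions <- unlist(user$split$fractions)
  }
  cfg
}

#' Run the tier-stratified multi-modal experiment
#'
#' For every risk tier present in the cohort and every requested feature
#' mode (semantic, count, joint): filter notes to the pre-index window,
#' tokenize, build the tier's feature matrices (the count vocabulary is fit
#' on the training partition only and applied frozen elsewhere), split
#' patients 64/16/20, run the randomized hyperparameter search with
#' patient-grouped cross-validation, and evaluate the selected model on the
#' withheld test partition at the document and patient level with bootstrap
#' confidence intervals. For the joint mode the alpha grid is swept and the
#' winner chosen by validation patient-level AUC; the result reports its
#' beta. Tiers whose partitions lack both classes are skipped with an
#' explicit entry.
#'
#' @param cohort cohort data.frame ([read_cohort()] shape).
#' @param notes notes data.frame ([read_notes()] shape).
#' @param lexicons a `lexicon` or list of lexicons for the semantic mode.
#' @param config configuration list ([default_config()]).
#' @param stopwords stopword vector.
#' @return object of class `risk_experiment`: per-tier results plus a
#'   comparison table (tier x mode AUC with CIs and joint beta).
#' @export
run_experiment <- function(cohort, notes, lexicons,
                           config = default_config(),
                           stopwords = default_stopwords()) {
  modes <- config$feature_mode
  notes_w <- filter_window(notes, cohort, config$window$min_days,
                           config$window$max_days)
  tiers <- levels(cohort$tier)[table(cohort$tier) > 0]
  results <- list()
  comparison <- list()
  for (tier in tiers) {
    tier_pat <- cohort[cohort$tier == tier, , drop = FALSE]
    tier_notes <- notes_w[notes_w$patient_id %in% tier_pat$patient_id, ,
                          drop = FALSE]
    scored_pat <- tier_pat[tier_pat$patient_id %in% tier_notes$patient_id, ,
                           drop = FALSE]
    res <- run_tier(tier, scored_pat, tier_notes, lexicons, config,
                    stopwords, modes)
    results[[tier]] <- res
    for (mode in names(res$modes)) {
      m <- res$modes[[mode]]
      comparison[[length(comparison) + 1L]] <- data.frame(
        tier = tier, mode = mode,
        auc = if (is.null(m$patient)) NA_real_ else m$patient$auc,
        ci_low = if (is.null(m$patient)) NA_real_ else m$patient$ci_low,
        ci_high = if (is.null(m$patient)) NA_real_ else m$patient$ci_high,
        beta = if (is.null(m$beta)) NA_real_ else m$beta,
        skipped = isTRUE(res$skipped),
        stringsAsFactors = FALSE
      )
    }
    if (isTRUE(res$skipped)) {
      comparison[[length(comparison) + 1L]] <- data.frame(
        tier = tier, mode = NA_character_, auc = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, beta = NA_real_,
        skipped = TRUE, stringsAsFactors = FALSE)
    }
  }
  structure(list(results = results,
                 comparison = do.call(rbind, comparison),
                 config = config),
            class = "risk_experiment")
}

# one tier x all modes; returns reports and fitted-model metadata
run_tier <- function(tier, cohort, notes, lexicons, config, stopwords,
                     modes) {
  if (sum(cohort$status == "case") < 2L ||
      sum(cohort$status == "control") < 2L || nrow(notes) == 0L) {
    return(list(skipped = TRUE, reason = "too few cases/controls with notes",
                modes = list()))
  }
  plan <- grouped_split(unique(cohort$patient_id),
                        fractions = config$split$fractions,
                        seed = config$split$seed)
  part <- note_partitions(plan, notes$patient_id)
  pat_part <- plan$partition[match(cohort$patient_id, plan$patient_id)]
  for (p in levels(part)) {
    st <- cohort$status[pat_part == p]
    if (sum(st == "case") < 2L || sum(st == "control") < 2L) {
      return(list(skipped = TRUE,
                  reason = sprintf("partition '%s' lacks both classes", p),
                  modes = list()))
    }
  }
  streams <- tokenize_notes(notes, stopwords)
  labels <- cohort$status[match(notes$patient_id, cohort$patient_id)]
  vocab <- fit_vocabulary(streams[part == "train"],
                          min_df = config$features$min_df,
                          max_df = config$features$max_df,
                          orders = config$features$ngram_orders)
  count_fm <- transform_counts(streams, vocab)
  if (identical(config$features$weighting, "tfidf")) {
    count_fm <- tfidf_transform(count_fm, vocab)
  }
  sem_fm <- featurize_semantic(streams, lexicons)
  spec <- search_spec(n_iterations = config$search$n_iterations,
                      cv_folds = config$search$cv_folds,
                      top_k = config$search$top_k,
                      seed = config$search$seed)
  out <- list()
  for (mode in modes) {
    out[[mode]] <- run_mode(mode, count_fm, sem_fm, labels, notes$patient_id,
                            part, cohort, config, spec)
  }
  list(skipped = FALSE, vocab_size = length(vocab$terms),
       n_semantic = ncol(sem_fm$x), split = plan, modes = out)
}

run_mode <- function(mode, count_fm, sem_fm, labels, note_patients, part,
                     cohort, config, spec) {
  tr <- part == "train"; va <- part == "validation"; te <- part == "test"
  fit_one <- function(fm, weights) {
    search_hyperparameters(subset_fm(fm, tr), labels[tr], note_patients[tr],
                           subset_fm(fm, va), labels[va], note_patients[va],
                           weights = weights, spec = spec,
                           class_weighting = config$model$class_weighting)
  }
  if (mode == "semantic") {
    fit <- fit_one(sem_fm, NULL); fm <- sem_fm; beta <- NULL; alpha <- NULL
  } else if (mode == "count") {
    fit <- fit_one(count_fm, NULL); fm <- count_fm; beta <- NULL
    alpha <- NULL
  } else if (mode == "joint") {
    fm <- merge_matrices(count_fm, sem_fm)
    grid <- config$fusion$alpha_grid
    fits <- lapply(grid, function(a) {
      fit_one(fm, compute_weights(sum(fm$set == "count"),
                                  sum(fm$set == "semantic"), a))
    })
    best <- which.max(vapply(fits, `[[`, 0, "validation_auc"))
    fit <- fits[[best]]
    alpha <- grid[best]
    beta <- beta_from_alpha(alpha)
  } else stop("unknown feature mode: ", mode)
  p_test <- predict(fit$model, subset_fm(fm, te))
  doc <- evaluation_report(p_test, labels[te], level = "document",
                           n_boot = config$evaluate$n_boot,
                           threshold = config$evaluate$threshold,
                           seed = config$evaluate$seed)
  test_cohort <- cohort[cohort$patient_id %in% note_patients[te], ,
                        drop = FALSE]
  agg <- aggregate_patients(p_test, note_patients[te], test_cohort)
  pat <- evaluation_report(agg$probability, agg$status, level = "patient",
                           n_boot = config$evaluate$n_boot,
                           threshold = config$evaluate$threshold,
                           seed = config$evaluate$seed)
  list(params = fit$params, validation_auc = fit$validation_auc,
       alpha = alpha, beta = beta, document = doc, patient = pat)
}

#' @export
print.risk_experiment <- function(x, ...) {
  cat("Tier-stratified model comparison (patient-level AUC [95% CI])\n")
  cmp <- x$comparison
  for (tier in unique(cmp$tier)) {
    sub <- cmp[cmp$tier == tier & !is.na(cmp$mode), , drop = FALSE]
    if (nrow(sub) == 0L || all(sub$skipped)) {
      cat(sprintf("  %-9s skipped (%s)\n", tier,
                  x$results[[tier]]$reason %||% "insufficient data"))
      next
    }
    cells <- vapply(seq_len(nrow(sub)), function(i) {
      s <- sprintf("%s %.2f [%.2f-%.2f]", sub$mode[i], sub$auc[i],
                   sub$ci_low[i], sub$ci_high[i])
      if (!is.na(sub$beta[i])) s <- paste0(s, sprintf(" (beta %.2f)",
                                                      sub$beta[i]))
      s
    }, "")
    cat(sprintf("  %-9s %s\n", tier, paste(cells, collapse = " | ")))
  }
  invisible(x)
}

#' @export
summary.risk_experiment <- function(object, ...) {
  print(object)
  for (tier in names(object$results)) {
    res <- object$results[[tier]]
    if (isTRUE(res$skipped)) next
    cat(sprintf("\n%s tier: %d count features, %d semantic features\n",
                tier, res$vocab_size, res$n_semantic))
    for (mode in names(res$modes)) {
      cat(sprintf("  [%s]\n", mode))
      print(res$modes[[mode]]$document)
      print(res$modes[[mode]]$patient)
    }
  }
  invisible(object)
}

#' Export an experiment report
#'
#' Writes `report.json` (full nested report), `report.csv` (one row per
#' tier x mode x level with the metric battery) and `manifest.json` (the
#' configuration, seeds, and per-tier vocabulary sizes).
#'
#' @param x a `risk_experiment`.
#' @param outdir output directory.
#' @export
write_report <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (tier in names(x$results)) {
    res <- x$results[[tier]]
    if (isTRUE(res$skipped)) next
    for (mode in names(res$modes)) {
      m <- res$modes[[mode]]
      for (lev in c("document", "patient")) {
        r <- m[[lev]]
        rows[[length(rows) + 1L]] <- data.frame(
          tier = tier, mode = mode, level = lev, auc = r$auc,
          ci_low = r$ci_low, ci_high = r$ci_high, n_boot = r$n_boot,
          beta = m$beta %||% NA_real_,
          brier = r$metrics$brier, accuracy = r$metrics$accuracy,
          precision = r$metrics$precision, recall = r$metrics$recall,
          specificity = r$metrics$specificity, ppv = r$metrics$ppv,
          npv = r$metrics$npv, f1 = r$metrics$f1,
          threshold = r$threshold, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(outdir, "report.csv"), row.names = FALSE)
  strip <- function(res) {
    if (isTRUE(res$skipped)) return(res["reason"])
    list(vocab_size = res$vocab_size, n_semantic = res$n_semantic,
         modes = lapply(res$modes, function(m) {
           list(params = m$params, alpha = m$alpha, beta = m$beta,
                validation_auc = m$validation_auc,
                document = unclass(m$document),
                patient = unclass(m$patient))
         }))
  }
  jsonlite::write_json(
    list(comparison = x$comparison,
         results = lapply(x$results, strip)),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(x$config, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
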