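#' Patient-grouped train/validation/test split
#'
#' Patients — not notes — are randomly partitioned, and every note inherits
#' its patient's partition, so no patient's text leaks across partitions.
#' Fractions follow the 64/16/20 convention: 80/20 train+validation vs test,
#' then 80/20 within the first part.
#'
#' @param patient_ids character vector of unique patient ids.
#' @param fractions named numeric `c(train=, validation=, test=)` summing
#'   to 1.
#' @param seed integer seed; the assignment is reproducible under it.
#' @param group optional grouping id per patient (e.g. `match_group`); when
#'   supplied, whole groups are allocated to one partition, keeping matched
#'   sets intact. With few matched sets per percentile, splitting a set
#'   across partitions makes train and test case-rates anticorrelated
#'   conditional on the matching variable, which biases null-calibration
#'   checks; group-level allocation avoids that.
#' @return object of class `split_plan`: data.frame with `patient_id` and
#'   `partition` (factor train/validation/test), plus the seed and fractions
#'   as attributes.
#' @export
grouped_split <- function(patient_ids,
                          fractions = c(train = 0.64, validation = 0.16,
                                        test = 0.20),
                          seed = 1L, group = NULL) {
  stopifnot(!anyDuplicated(patient_ids), all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8,
            identical(names(fractions), c("train", "validation", "test")))
  if (!is.null(group)) {
    stopifnot(length(group) == length(patient_ids))
    units <- unique(group)
    gplan <- grouped_split(units, fractions, seed)
    part <- as.character(gplan$partition[match(group, gplan$patient_id)])
    return(structure(data.frame(patient_id = patient_ids,
                                partition = factor(part,
                                                   levels = c("train",
                                                              "validation",
                                                              "test")),
                                stringsAsFactors = FALSE),
                     seed = seed, fractions = fractions,
                     class = c("split_plan", "data.frame")))
  }
  n <- length(patient_ids)
  ord <- local({ set.seed(seed); sample.int(n) })
  n_train <- round(fractions[["train"]] * n)
  n_val <- round(fractions[["validation"]] * n)
  part <- rep("test", n)
  part[ord <= n_train] <- "train"
  part[ord > n_train & ord <= n_train + n_val] <- "validation"
  structure(data.frame(patient_id = patient_ids,
                       partition = factor(part, levels = c("train",
                                                           "validation",
                                                           "test")),
                       stringsAsFactors = FALSE),
            seed = seed, fractions = fractions,
            class = c("split_plan", "data.frame"))
}

#' Map notes to their patient's partition
#' @param plan a `split_plan`.
#' @param note_patients patient id per note.
#' @return factor of partitions, one per note.
#' @export
note_partitions <- function(plan, note_patients) {
  unknown <- setdiff(note_patients, plan$patient_id)
  if (length(unknown)) stop("notes reference patients outside the split: ",
                            paste(utils::head(unknown, 5L), collapse = ", "))
  plan$partition[match(note_patients, plan$patient_id)]
}

#' Default boosted-tree hyperparameters
#'
#' `colsample_bynode < 1` is required for the per-feature selection weights
#' to influence which features are offered at each node split.
#'
#' @return named list.
#' @export
default_params <- function() {
  list(max_depth = 4L, eta = 0.1, nrounds = 150L, subsample = 0.9,
       colsample_bynode = 0.5, min_child_weight = 1)
}

#' Train the note-level boosted-tree classifier
#'
#' Fits a binary gradient-boosted tree model (XGBoost) on note-level rows.
#' No normalization or imputation is applied — trees split raw values and
#' handle missing entries natively. When a `weighting_scheme` is supplied,
#' its per-feature selection weights bias which columns are sampled as
#' candidates at each node split (semantic columns get
#' `(n_count/n_semantic)*alpha`, count columns 1). Class imbalance from 1:k
#' matching is absorbed by a positive-class weight `n_control/n_case` by
#' default. Training is single-threaded and deterministic under the seed.
#'
#' @param fm `feature_matrix` (or plain matrix with dimnames) of training
#'   rows.
#' @param labels per-note labels: `"case"`/`"control"`, logical, or 0/1
#'   (case = 1).
#' @param weights optional `weighting_scheme` (joint matrices).
#' @param params hyperparameter list as in [default_params()].
#' @param seed integer seed.
#' @param class_weighting logical; scale the positive class by the
#'   control:case ratio.
#' @return object of class `note_model`.
#' @export
train_classifier <- function(fm, labels, weights = NULL,
                             params = default_params(), seed = 1L,
                             class_weighting = TRUE) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  y <- as_label01(labels)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  stopifnot(nrow(x) == length(y))
  fw <- if (is.null(weights)) rep(1, ncol(x)) else {
    stopifnot(inherits(fm, "feature_matrix"))
    column_weights(fm, weights)
  }
  params <- utils::modifyList(default_params(), params)
  nrounds <- params$nrounds
  params$nrounds <- NULL
  spw <- if (class_weighting) sum(y == 0) / sum(y == 1) else 1
  dtrain <- xgboost::xgb.DMatrix(to_dmatrix_input(x), label = y,
                                 feature_weights = fw)
  booster <- xgboost::xgb.train(
    params = c(params, list(objective = "binary:logistic",
                            scale_pos_weight = spw,
                            nthread = 1L, seed = seed)),
    data = dtrain, nrounds = nrounds, verbose = 0)
  structure(list(booster = booster,
                 feature_names = colnames(x),
                 set = if (inherits(fm, "feature_matrix")) fm$set else
                   rep("count", ncol(x)),
                 weights = weights,
                 params = c(params, nrounds = nrounds),
                 seed = seed,
                 n_train = nrow(x)),
            class = "note_model")
}

as_label01 <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("case", "control"))
    if (length(bad)) stop("labels must be 'case'/'control'; got: ",
                          paste(bad, collapse = ", "))
    return(as.integer(labels == "case"))
  }
  y <- as.integer(labels)
  stopifnot(all(y %in% 0:1))
  y
}

to_dmatrix_input <- function(x) {
  if (methods::is(x, "Matrix")) {
    methods::as(methods::as(x, "dMatrix"), "CsparseMatrix")
  } else {
    as.matrix(x)
  }
}

#' @export
print.note_model <- function(x, ...) {
  cat(sprintf("<note_model> %d features (%d count, %d semantic), %d training notes\n",
              length(x$feature_names), sum(x$set == "count"),
              sum(x$set == "semantic"), x$n_train))
  if (!is.null(x$weights)) print(x$weights)
  invisible(x)
}

#' Note-level predicted probabilities
#'
#' @param object a `note_model`.
#' @param newdata `feature_matrix` (or matrix) whose columns match training
#'   columns in name and order.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\], named by note id.
#' @export
predict.note_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  if (!identical(colnames(x), object$feature_names)) {
    missing_ <- setdiff(object$feature_names, colnames(x))
    extra <- setdiff(colnames(x), object$feature_names)
    stop("column mismatch with training matrix;",
         if (length(missing_)) paste0(" missing: ",
           paste(utils::head(missing_, 5L), collapse = ", ")),
         if (length(extra)) paste0(" extra: ",
           paste(utils::head(extra, 5L), collapse = ", ")),
         if (!length(missing_) && !length(extra)) " columns are reordered")
  }
  p <- predict(object$booster, xgboost::xgb.DMatrix(to_dmatrix_input(x)))
  names(p) <- rownames(x)
  p
}

#' @rdname predict.note_model
#' @param model a `note_model`.
#' @param fm feature matrix to score.
#' @export
predict_notes <- function(model, fm) predict(model, fm)

#' Fraction of tree splits using semantic features
#'
#' Diagnostic for the alpha weighting: parses the fitted trees and returns
#' the proportion of internal split nodes whose split feature is tagged
#' semantic. Under weight-proportional candidate sampling this fraction
#' rises monotonically with alpha.
#'
#' @param model a `note_model`.
#' @return proportion in \[0, 1\] (NaN if the model has no splits).
#' @export
semantic_split_fraction <- function(model) {
  tt <- xgboost::xgb.model.dt.tree(model = model$booster)
  splits <- tt$Feature[tt$Feature != "Leaf"]
  sem <- model$feature_names[model$set == "semantic"]
  if (length(splits) == 0L) return(NaN)
  mean(splits %in% sem)
}

#' Randomized hyperparameter search specification
#'
#' @param n_iterations number of random configurations (default 100).
#' @param cv_folds patient-grouped cross-validation folds for the coarse
#'   ranking pass (default 5).
#' @param top_k configurations carried from the coarse pass to final
#'   selection on the validation partition.
#' @param seed integer seed.
#' @param ranges named list of sampling ranges; see [default_search_ranges()].
#' @return object of class `search_spec`.
#' @export
search_spec <- function(n_iterations = 100L, cv_folds = 5L, top_k = 5L,
                        seed = 1L, ranges = default_search_ranges()) {
  stopifnot(n_iterations >= 1L, cv_folds >= 2L, top_k >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 cv_folds = as.integer(cv_folds),
                 top_k = min(as.integer(top_k), as.integer(n_iterations)),
                 seed = as.integer(seed), ranges = ranges),
            class = "search_spec")
}

#' Default hyperparameter sampling ranges
#'
#' Tree depth 2-10, learning rate log-uniform on \[0.01, 0.3\], 50-500
#' trees, subsample and per-node column-sample rates 0.5-1, minimum child
#' weight 1-10.
#'
#' @return named list of `c(lo, hi)` ranges.
#' @export
default_search_ranges <- function() {
  list(max_depth = c(2L, 10L), eta = c(0.01, 0.3), nrounds = c(50L, 500L),
       subsample = c(0.5, 1.0), colsample_bynode = c(0.5, 1.0),
       min_child_weight = c(1, 10))
}

sample_config <- function(ranges) {
  list(max_depth = sample(ranges$max_depth[1]:ranges$max_depth[2], 1L),
       eta = exp(stats::runif(1, log(ranges$eta[1]), log(ranges$eta[2]))),
       nrounds = sample(ranges$nrounds[1]:ranges$nrounds[2], 1L),
       subsample = stats::runif(1, ranges$subsample[1], ranges$subsample[2]),
       colsample_bynode = stats::runif(1, ranges$colsample_bynode[1],
                                       ranges$colsample_bynode[2]),
       min_child_weight = stats::runif(1, ranges$min_child_weight[1],
                                       ranges$min_child_weight[2]))
}

#' Randomized hyperparameter search with patient-grouped selection
#'
#' Two-stage selection: a coarse pass scores each sampled configuration by
#' patient-grouped k-fold cross-validation on the training rows (mean
#' patient-level AUC over held-out folds); the top configurations are then
#' refit on the full training partition and the final model is the one with
#' the best patient-level AUC on the withheld validation partition.
#'
#' @param train_fm,val_fm training / validation `feature_matrix`.
#' @param train_labels,val_labels per-note labels.
#' @param train_patients,val_patients patient id per note.
#' @param weights optional `weighting_scheme`.
#' @param spec a [search_spec()].
#' @param class_weighting passed to [train_classifier()].
#' @return list with `model` (the refit `note_model`), `params`, and
#'   `validation_auc`.
#' @export
search_hyperparameters <- function(train_fm, train_labels, train_patients,
                                   val_fm, val_labels, val_patients,
                                   weights = NULL, spec = search_spec(),
                                   class_weighting = TRUE) {
  if (length(unique(as_label01(val_labels))) < 2L) {
    stop("validation partition lacks one of the classes")
  }
  set.seed(spec$seed)
  configs <- replicate(spec$n_iterations, sample_config(spec$ranges),
                       simplify = FALSE)
  pats <- unique(train_patients)
  fold_of <- sample(rep_len(seq_len(spec$cv_folds), length(pats)))
  names(fold_of) <- pats
  note_fold <- fold_of[train_patients]
  cv_score <- vapply(seq_along(configs), function(ci) {
    aucs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- note_fold != f
      if (length(unique(as_label01(train_labels)[tr])) < 2L ||
          length(unique(as_label01(train_labels)[!tr])) < 2L) return(NA_real_)
      m <- train_classifier(subset_fm(train_fm, tr), train_labels[tr],
                            weights = weights, params = configs[[ci]],
                            seed = spec$seed + ci,
                            class_weighting = class_weighting)
      p <- predict(m, subset_fm(train_fm, !tr))
      patient_auc(p, train_patients[!tr], train_labels[!tr])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  order_cv <- order(cv_score, decreasing = TRUE)
  finalists <- order_cv[seq_len(min(spec$top_k, length(configs)))]
  val_auc <- rep(NA_real_, length(finalists))
  fits <- vector("list", length(finalists))
  for (i in seq_along(finalists)) {
    ci <- finalists[i]
    fits[[i]] <- train_classifier(train_fm, train_labels, weights = weights,
                                  params = configs[[ci]],
                                  seed = spec$seed + ci,
                                  class_weighting = class_weighting)
    p <- predict(fits[[i]], val_fm)
    val_auc[i] <- patient_auc(p, val_patients, val_labels)
  }
  best <- which.max(val_auc)
  list(model = fits[[best]], params = configs[[finalists[best]]],
       validation_auc = val_auc[best])
}

#' Subset feature-matrix rows by logical or integer index
#' @param fm `feature_matrix` or plain matrix.
#' @param idx row index.
#' @return object of the same kind restricted to those rows.
#' @export
subset_fm <- function(fm, idx) {
  if (inherits(fm, "feature_matrix")) {
    feature_matrix(fm$x[idx, , drop = FALSE], fm$set)
  } else {
    fm[idx, , drop = FALSE]
  }
}

#' Patient-level AUC from note-level probabilities
#'
#' Convenience composition of [aggregate_patients()] and [roc_auc()]: note
#' probabilities are averaged per patient and the concordance AUC is
#' computed on the patient means. Returns `NA` when the aggregated patients
#' are single-class.
#'
#' @param note_probs note-level probabilities.
#' @param note_patients patient id per note.
#' @param note_labels per-note case/control labels (a note's label is its
#'   patient's status).
#' @return AUC in \[0, 1\] or `NA`.
#' @export
patient_auc <- function(note_probs, note_patients, note_labels) {
  agg <- stats::aggregate(list(p = note_probs),
                          by = list(patient_id = note_patients), FUN = mean)
  lab <- as_label01(note_labels)[match(agg$patient_id, note_patients)]
  if (length(unique(lab)) < 2L) return(NA_real_)
  roc_auc(agg$p, lab)
}
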