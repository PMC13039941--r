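#' Convert the semantic weighting multiplier alpha to beta
#'
#' beta = alpha / (alpha + 1) is the probability that a semantic (as opposed
#' to a count) feature is sampled as a split candidate once the weight
#' w = (n_count / n_semantic) * alpha has corrected for the feature-set size
#' imbalance. beta is the natural reporting axis: it is bounded in \[0, 1)
#' and beta = 0.5 means both feature sets are equally likely to be offered
#' at a node split.
#'
#' @param alpha nonnegative numeric (vectorized).
#' @return beta values in \[0, 1).
#' @examples
#' beta_from_alpha(c(0.6, 1, 5))
#' @export
beta_from_alpha <- function(alpha) {
  if (any(alpha < 0)) stop("alpha must be nonnegative")
  alpha / (alpha + 1)
}

#' Half-up decimal rounding for printed tables
#'
#' Conventional round-half-up at a fixed number of decimals, the convention
#' used when printing beta values (so beta = 0.375 prints as 0.38). Base
#' `round()` rounds half to even and is sensitive to binary representation
#' right at the half boundary, which is exactly where the alpha grid's
#' beta = 0.6/1.6 lands.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2L) {
  s <- 10^digits
  floor(x * s + 0.5 + sqrt(.Machine$double.eps)) / s
}

#' Default alpha grid
#'
#' Nine values spanning strong count-dominance to strong semantic-dominance;
#' the equivalent beta values, rounded to 2 decimals, are 0.01, 0.03, 0.06,
#' 0.09, 0.23, 0.38, 0.50, 0.71, 0.83.
#'
#' @return numeric vector.
#' @export
default_alpha_grid <- function() {
  c(0.01, 0.03, 0.06, 0.10, 0.30, 0.60, 1.00, 2.50, 5.00)
}

#' Compute per-feature-set selection weights
#'
#' Count features keep weight 1; semantic features get
#' w = (n_count / n_semantic) * alpha, so that at alpha = 1 the two feature
#' sets as a whole are equally likely to contribute a sampled split
#' candidate despite their very different sizes. The weights are relative
#' sampling propensities, not probabilities; the learner normalizes them.
#'
#' @param n_count,n_semantic feature tallies (>= 1).
#' @param alpha positive semantic multiplier.
#' @return object of class `weighting_scheme`: list with `alpha`, `beta`,
#'   `n_count`, `n_semantic`, `count_weight` (= 1), `semantic_weight`.
#' @export
compute_weights <- function(n_count, n_semantic, alpha) {
  stopifnot(n_count >= 1L, n_semantic >= 1L)
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(alpha = alpha,
                 beta = beta_from_alpha(alpha),
                 n_count = as.integer(n_count),
                 n_semantic = as.integer(n_semantic),
                 count_weight = 1,
                 semantic_weight = (n_count / n_semantic) * alpha),
            class = "weighting_scheme")
}

#' @export
print.weighting_scheme <- function(x, ...) {
  cat(sprintf(
    "<weighting_scheme> alpha=%g beta=%.3f | %d count @ w=1, %d semantic @ w=%.4f\n",
    x$alpha, x$beta, x$n_count, x$n_semantic, x$semantic_weight))
  invisible(x)
}

#' Per-column selection weight vector for a joint matrix
#' @param fm a `feature_matrix` (typically joint).
#' @param scheme a `weighting_scheme`.
#' @return numeric vector aligned to the columns of `fm`.
#' @export
column_weights <- function(fm, scheme) {
  stopifnot(inherits(fm, "feature_matrix"),
            inherits(scheme, "weighting_scheme"))
  ifelse(fm$set == "semantic", scheme$semantic_weight, scheme$count_weight)
}

#' Horizontally merge count and semantic feature matrices
#'
#' Columns are concatenated; rows are aligned by note id (the count
#' matrix's row order wins). Feature-name collisions across sets are
#' resolved by prefixing with the set tag. Both inputs must cover exactly
#' the same notes.
#'
#' @param count_m `feature_matrix` tagged count.
#' @param semantic_m `feature_matrix` tagged semantic.
#' @return joint `feature_matrix` with mixed column tags.
#' @export
merge_matrices <- function(count_m, semantic_m) {
  stopifnot(inherits(count_m, "feature_matrix"),
            inherits(semantic_m, "feature_matrix"))
  a <- rownames(count_m$x); b <- rownames(semantic_m$x)
  orphan <- c(setdiff(a, b), setdiff(b, a))
  if (length(orphan)) {
    stop("row sets differ; orphan note_id(s): ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  sm <- semantic_m$x[a, , drop = FALSE]
  cn <- colnames(count_m$x); sn <- colnames(sm)
  clash <- intersect(cn, sn)
  if (length(clash)) {
    cn[cn %in% clash] <- paste0("count.", cn[cn %in% clash])
    sn[sn %in% clash] <- paste0("semantic.", sn[sn %in% clash])
  }
  x <- cbind(methods::as(methods::as(count_m$x, "dMatrix"), "CsparseMatrix"),
             methods::as(methods::as(Matrix::Matrix(sm), "dMatrix"),
                         "CsparseMatrix"))
  colnames(x) <- c(cn, sn)
  feature_matrix(x, c(count_m$set, semantic_m$set))
}
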