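#' Construct a feature matrix
#'
#' Thin container pairing a (sparse-capable) numeric matrix of documents x
#' features with a per-column feature-set tag (`"count"` or `"semantic"`).
#' Row names are note ids; column names are feature names and must be unique.
#'
#' @param x matrix or `Matrix` with dimnames set.
#' @param set either a single tag recycled over columns or a per-column
#'   character vector.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, set) {
  stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
  if (anyDuplicated(colnames(x))) stop("feature names must be unique")
  if (length(set) == 1L) set <- rep(set, ncol(x))
  stopifnot(length(set) == ncol(x), all(set %in% c("count", "semantic")))
  structure(list(x = x, set = set), class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
dimnames.feature_matrix <- function(x) dimnames(x$x)

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$set)
  cat(sprintf("<feature_matrix> %d notes x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Subset the rows of a feature matrix by note id
#' @param fm feature_matrix.
#' @param note_ids character vector of row names to keep, in order.
#' @return feature_matrix restricted to those rows.
#' @export
fm_rows <- function(fm, note_ids) {
  miss <- setdiff(note_ids, rownames(fm$x))
  if (length(miss)) stop("unknown note_id(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  feature_matrix(fm$x[note_ids, , drop = FALSE], fm$set)
}

#' Export a feature matrix as MatrixMarket plus sidecar name files
#'
#' Writes `<stem>.mtx`, `<stem>.rows` (note ids), `<stem>.cols`
#' (tab-separated feature name and set tag).
#'
#' @param fm feature_matrix.
#' @param stem output path stem.
#' @export
write_feature_matrix <- function(fm, stem) {
  m <- methods::as(methods::as(fm$x, "dMatrix"), "generalMatrix")
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paste0(stem, ".mtx"))
  writeLines(rownames(fm$x), paste0(stem, ".rows"))
  writeLines(paste(colnames(fm$x), fm$set, sep = "\t"), paste0(stem, ".cols"))
  invisible(stem)
}
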