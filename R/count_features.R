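#' Fit an n-gram vocabulary with document-frequency filtering
#'
#' Document frequency counts presence, not multiplicity. A term is retained
#' iff `min_df <= doc_freq(term) <= floor(max_df * n_docs)`: "occurring in
#' more than `max_df` of documents" is read strictly, so a term sitting
#' exactly on the proportional ceiling survives. Retained terms are ordered
#' lexicographically (byte order) for reproducibility.
#'
#' @param corpus list of `token_stream`s (or plain token vectors).
#' @param min_df absolute lower document-frequency threshold (default 100,
#'   the convention for large clinical corpora; lower it for small corpora).
#' @param max_df proportional upper threshold in (0, 1].
#' @param orders n-gram orders passed to [build_ngrams()].
#' @return object of class `vocabulary`: list with `terms`, `doc_freq`,
#'   `n_docs_fit`, `min_df`, `max_df`, `orders`.
#' @export
fit_vocabulary <- function(corpus, min_df = 100L, max_df = 0.9,
                           orders = c(1L, 2L)) {
  stopifnot(length(corpus) > 0L, min_df >= 1L, max_df > 0, max_df <= 1)
  per_doc <- lapply(corpus, function(s) unique(build_ngrams(s, orders)))
  df <- table(unlist(per_doc, use.names = FALSE))
  n <- length(corpus)
  keep <- df >= min_df & df <= floor(max_df * n)
  terms <- sort(names(df)[keep], method = "radix")
  if (length(terms) == 0L) {
    warning("document-frequency filter removed every term; empty vocabulary")
  }
  structure(list(terms = terms,
                 doc_freq = as.integer(df[terms]),
                 n_docs_fit = n, min_df = as.integer(min_df),
                 max_df = max_df, orders = orders),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d terms (min_df=%d, max_df=%g, fit on %d docs)\n",
              length(x$terms), x$min_df, x$max_df, x$n_docs_fit))
  invisible(x)
}

#' Transform a corpus into a document-term count matrix
#'
#' Cell (d, t) is the number of occurrences of vocabulary term t in document
#' d. Out-of-vocabulary terms are ignored; documents with no in-vocabulary
#' terms give all-zero rows.
#'
#' @param corpus list of `token_stream`s; names (or stream `note_id`s) become
#'   row names.
#' @param vocab a fitted [fit_vocabulary()] object.
#' @return sparse `feature_matrix` tagged `"count"`.
#' @export
transform_counts <- function(corpus, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  ids <- names(corpus)
  if (is.null(ids)) {
    ids <- vapply(corpus, function(s)
      if (inherits(s, "token_stream")) s$note_id else NA_character_, "")
  }
  if (anyDuplicated(ids) || any(is.na(ids))) {
    stop("corpus must carry unique note ids")
  }
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_along(corpus)) {
    tf <- table(match(build_ngrams(corpus[[d]], vocab$orders), vocab$terms))
    tf <- tf[names(tf) != "NA" & !is.na(names(tf))]
    if (length(tf)) {
      ii <- c(ii, rep.int(d, length(tf)))
      jj <- c(jj, as.integer(names(tf)))
      xx <- c(xx, as.integer(tf))
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(corpus), length(vocab$terms)),
                            dimnames = list(ids, vocab$terms))
  feature_matrix(m, "count")
}

#' TF-IDF reweighting of a count matrix
#'
#' Smoothed inverse document frequency, `idf(t) = ln((1 + n) / (1 + df(t)))
#' + 1` with n the fit-time corpus size, applied to raw counts, then each
#' row L2-normalized (zero rows stay zero). Offered as an alternative to raw
#' counts; counts are the default weighting as they tend to classify
#' clinical notes marginally better.
#'
#' @param counts a `feature_matrix` from [transform_counts()].
#' @param vocab the vocabulary the counts were produced under.
#' @return `feature_matrix` tagged `"count"` with TF-IDF values.
#' @export
tfidf_transform <- function(counts, vocab) {
  stopifnot(inherits(counts, "feature_matrix"), inherits(vocab, "vocabulary"),
            identical(colnames(counts$x), vocab$terms))
  idf <- log((1 + vocab$n_docs_fit) / (1 + vocab$doc_freq)) + 1
  m <- counts$x %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  m <- Matrix::Diagonal(x = 1 / norms) %*% m
  dimnames(m) <- dimnames(counts$x)
  feature_matrix(m, "count")
}

#' Serialize a vocabulary as TSV (term, doc_freq)
#' @param vocab vocabulary object.
#' @param path output path.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(data.frame(term = vocab$terms, doc_freq = vocab$doc_freq),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
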