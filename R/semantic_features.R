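#' Default negation cue tokens
#'
#' Cues that suppress a lexicon match when they occur within the lookback
#' window immediately preceding it.
#'
#' @return lowercase character vector.
#' @export
default_negators <- function() {
  c("no", "not", "never", "denies", "denied", "without", "n't")
}

#' Construct a lexicon in memory
#'
#' A lexicon is a named collection of categories; each category is a set of
#' lowercase unigram terms with a polarity tag and a list of negation window
#' sizes for which a `_neg_k` variant feature is emitted.
#'
#' @param name lexicon name (used as the feature-name prefix).
#' @param categories named list; each element a list with `terms`
#'   (character), `polarity` (`"positive"`/`"negative"`/`"neutral"`), and
#'   `negation_variants` (integer vector, possibly empty).
#' @return object of class `lexicon`.
#' @export
lexicon <- function(name, categories) {
  stopifnot(is.character(name), length(categories) > 0L,
            !is.null(names(categories)))
  categories <- lapply(categories, function(cat) {
    terms <- tolower(cat$terms)
    if (length(terms) == 0L) stop("lexicon category with empty term list")
    if (anyDuplicated(terms)) {
      warning("duplicate terms in a lexicon category; deduplicated")
      terms <- unique(terms)
    }
    pol <- if (is.null(cat$polarity)) "neutral" else cat$polarity
    stopifnot(pol %in% c("positive", "negative", "neutral"))
    nv <- as.integer(cat$negation_variants %||% integer(0))
    if (any(nv < 1L)) stop("negation window sizes must be >= 1")
    list(terms = terms, polarity = pol, negation_variants = nv)
  })
  structure(list(name = name, categories = categories), class = "lexicon")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s'> %d categories, %d terms\n", x$name,
              length(x$categories),
              sum(vapply(x$categories, function(c) length(c$terms), 1L))))
  invisible(x)
}

#' Load a lexicon from a TSV or JSON file
#'
#' TSV format: header `lexicon, category_id, polarity, negation_variants,
#' terms`, one category per row, with `negation_variants` a comma-separated
#' integer list (may be empty) and `terms` a semicolon-separated token list.
#' A `.json` file may instead hold `{"name": ..., "categories": {id:
#' {"terms": [...], "polarity": ..., "negation_variants": [...]}}}`.
#'
#' @param path file path.
#' @return a `lexicon` object.
#' @export
load_lexicon <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    return(lexicon(spec$name, spec$categories))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("lexicon", "category_id", "polarity", "negation_variants", "terms")
  if (!all(need %in% names(df))) {
    stop("lexicon file must have columns: ", paste(need, collapse = ", "))
  }
  cats <- list()
  for (i in seq_len(nrow(df))) {
    terms <- strsplit(df$terms[i], ";", fixed = TRUE)[[1]]
    terms <- trimws(terms[nzchar(trimws(terms))])
    if (length(terms) == 0L) {
      stop("line ", i + 1L, ": category '", df$category_id[i],
           "' has an empty term list")
    }
    nv <- df$negation_variants[i]
    nv <- if (is.na(nv) || !nzchar(trimws(as.character(nv)))) integer(0) else
      as.integer(strsplit(as.character(nv), ",", fixed = TRUE)[[1]])
    if (anyNA(nv)) stop("line ", i + 1L, ": malformed negation_variants")
    cats[[df$category_id[i]]] <- list(terms = terms,
                                      polarity = df$polarity[i],
                                      negation_variants = nv)
  }
  lexicon(df$lexicon[1], cats)
}

#' Score one document against one lexicon category
#'
#' The base score is the proportion of (stopword-removed) token positions
#' matching the category's term set; an empty document scores 0. With a
#' negation window `negation_k = k`, a match is suppressed when any negation
#' cue occurs within the k tokens immediately preceding it in the raw,
#' pre-stopword sequence — the raw sequence is used because common cues
#' ("no", "not") are themselves stopwords.
#'
#' @param stream a `token_stream` from [tokenize()].
#' @param category one element of `lexicon$categories` (list with `terms`).
#' @param negation_k `NULL` for the base score, or an integer window size.
#' @param negators negation cue set; [default_negators()] by default.
#' @return score in \[0, 1\].
#' @export
score_document <- function(stream, category, negation_k = NULL,
                           negators = default_negators()) {
  stopifnot(inherits(stream, "token_stream"))
  n <- length(stream$tokens)
  if (n == 0L) return(0)
  hit <- stream$tokens %in% category$terms
  if (!is.null(negation_k) && any(hit)) {
    stopifnot(negation_k >= 1L)
    neg_pos <- which(stream$raw %in% negators)
    if (length(neg_pos)) {
      for (idx in which(hit)) {
        p <- stream$raw_pos[idx]
        if (any(neg_pos >= p - negation_k & neg_pos < p)) hit[idx] <- FALSE
      }
    }
  }
  sum(hit) / n
}

#' Closed-vocabulary featurization of a corpus
#'
#' One column per category x negation-variant: `<lexicon>.<category>` for
#' the base score and `<lexicon>.<category>_neg_<k>` for each window size k
#' in the category's `negation_variants`. Values are [score_document()]
#' proportions.
#'
#' @param corpus named list of `token_stream`s.
#' @param lexicons a `lexicon` or list of lexicons.
#' @param negators negation cue set.
#' @return dense `feature_matrix` tagged `"semantic"`.
#' @export
featurize_semantic <- function(corpus, lexicons,
                               negators = default_negators()) {
  if (inherits(lexicons, "lexicon")) lexicons <- list(lexicons)
  ids <- names(corpus)
  if (is.null(ids)) ids <- vapply(corpus, `[[`, "", "note_id")
  cols <- list()
  for (lex in lexicons) {
    for (cid in names(lex$categories)) {
      cat_ <- lex$categories[[cid]]
      variants <- c(list(NULL), as.list(cat_$negation_variants))
      for (k in variants) {
        nm <- if (is.null(k)) paste0(lex$name, ".", cid) else
          sprintf("%s.%s_neg_%d", lex$name, cid, k)
        cols[[nm]] <- vapply(corpus, score_document, 0,
                             category = cat_, negation_k = k,
                             negators = negators)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  feature_matrix(m, "semantic")
}
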