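#' Default English stopword list
#'
#' A standard function-word inventory (pronouns, auxiliaries, articles,
#' prepositions, conjunctions). Negation cues such as "no"/"not" are on the
#' list — they carry no topical content as tokens — but negation handling in
#' the lexicon scorer looks back over the raw, pre-stopword sequence, so
#' removing them here does not disable negation control.
#'
#' @return character vector of lowercase stopwords.
#' @export
default_stopwords <- function() {
  c("i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his",
    "himself", "she", "her", "hers", "herself", "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves", "what", "which",
    "who", "whom", "this", "that", "these", "those", "am", "is", "are",
    "was", "were", "be", "been", "being", "have", "has", "had", "having",
    "do", "does", "did", "doing", "a", "an", "the", "and", "but", "if",
    "or", "because", "as", "until", "while", "of", "at", "by", "for",
    "with", "about", "against", "between", "into", "through", "during",
    "before", "after", "above", "below", "to", "from", "up", "down", "in",
    "out", "on", "off", "over", "under", "again", "further", "then",
    "once", "here", "there", "when", "where", "why", "how", "all", "any",
    "both", "each", "few", "more", "most", "other", "some", "such", "no",
    "nor", "not", "only", "own", "same", "so", "than", "too", "very",
    "s", "t", "can", "could", "will", "would", "shall", "should", "may",
    "might", "must", "just", "now")
}

#' Read a stopword list from a plain-text file (one token per line)
#' @param path file path.
#' @return lowercase character vector.
#' @export
read_stopwords <- function(path) {
  x <- tolower(trimws(readLines(path, warn = FALSE)))
  unique(x[nzchar(x)])
}

#' Tokenize note text
#'
#' Lowercases, splits on runs of non-alphanumeric characters (apostrophes
#' and other punctuation act as separators; digits are retained), then
#' removes stopwords. The raw pre-stopword sequence and the raw positions of
#' the surviving tokens are kept alongside, because downstream negation
#' lookback must see cues that are themselves stopwords.
#'
#' @param text a single character string.
#' @param stopwords character vector of stopwords; [default_stopwords()] by
#'   default.
#' @param note_id optional identifier carried on the result.
#' @return a `token_stream`: list with `note_id`, `raw` (all tokens),
#'   `tokens` (stopword-removed, in order) and `raw_pos` (index of each
#'   surviving token in `raw`).
#' @examples
#' tokenize("Patient WAS anxious and tearful")$tokens
#' @export
tokenize <- function(text, stopwords = default_stopwords(), note_id = NA_character_) {
  stopifnot(length(text) == 1L)
  raw <- regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
  keep <- !(raw %in% stopwords)
  structure(list(note_id = note_id,
                 raw = raw,
                 tokens = raw[keep],
                 raw_pos = which(keep)),
            class = "token_stream")
}

#' Tokenize a set of notes
#'
#' @param notes notes data.frame (`note_id`, `text`).
#' @param stopwords stopword vector passed to [tokenize()].
#' @return named list of `token_stream`s, one per note, names = note ids.
#' @export
tokenize_notes <- function(notes, stopwords = default_stopwords()) {
  out <- lapply(seq_len(nrow(notes)), function(i) {
    tokenize(notes$text[i], stopwords, note_id = notes$note_id[i])
  })
  names(out) <- notes$note_id
  out
}

#' @export
print.token_stream <- function(x, ...) {
  cat("<token_stream", if (!is.na(x$note_id)) x$note_id, ">",
      length(x$tokens), "tokens (", length(x$raw), "pre-stopword )\n")
  invisible(x)
}

#' Build unigrams and/or adjacent bigrams from a token stream
#'
#' Bigrams are formed over the stopword-removed sequence and join the two
#' tokens with a single space, so "alcohol and suicide" yields the bigram
#' "alcohol suicide".
#'
#' @param stream a `token_stream` from [tokenize()], or a plain character
#'   vector of tokens.
#' @param orders subset of `c(1, 2)`: which n-gram orders to emit.
#' @return character vector of n-gram strings, unigrams first.
#' @export
build_ngrams <- function(stream, orders = c(1L, 2L)) {
  toks <- if (inherits(stream, "token_stream")) stream$tokens else stream
  stopifnot(all(orders %in% 1:2))
  out <- character(0)
  if (1L %in% orders) out <- c(out, toks)
  if (2L %in% orders && length(toks) >= 2L) {
    n <- length(toks)
    out <- c(out, paste(toks[-n], toks[-1]))
  }
  out
}
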