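# Small in-code fixtures shared across test files.

# token_stream built directly from a token vector (no stopword removal),
# for oracle tests that control the sequence exactly
stream_from_tokens <- function(tokens, raw = tokens,
                               note_id = "n1") {
  keep <- match(tokens, raw)
  structure(list(note_id = note_id, raw = raw, tokens = tokens,
                 raw_pos = if (length(tokens)) keep else integer(0)),
            class = "token_stream")
}

# tiny matched cohort: n_cases cases x k controls, one percentile each
tiny_cohort <- function(n_cases = 4L, k = 2L, percentile = 10L,
                        index = as.Date("2017-06-01")) {
  n <- n_cases * (k + 1L)
  grp <- rep(seq_len(n_cases), each = k + 1L)
  df <- data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    status = rep(c("case", rep("control", k)), n_cases),
    index_date = index,
    percentile = percentile,
    match_group = sprintf("mg%02d", grp),
    stringsAsFactors = FALSE
  )
  df$tier <- assign_tier(df$percentile)
  df
}

# notes data.frame with given day offsets before a shared index date
notes_at_days <- function(days, patient_id = "p001",
                          index = as.Date("2017-06-01"),
                          text = "lorem ipsum") {
  data.frame(
    note_id = sprintf("n%03d", seq_along(days)),
    patient_id = patient_id,
    note_date = index - days,
    text = text,
    stringsAsFactors = FALSE
  )
}

# random token streams over a small alphabet, named by note id
random_corpus <- function(n_docs, vocab = letters, len = 8L) {
  out <- lapply(seq_len(n_docs), function(i) {
    toks <- sample(vocab, max(1L, rpois(1L, len)), replace = TRUE)
    stream_from_tokens(toks, note_id = sprintf("n%03d", i))
  })
  names(out) <- vapply(out, `[[`, "", "note_id")
  out
}

fixture_lexicon_path <- function() {
  system.file("extdata", "synthetic_lexicon.tsv", package = "riskfuse")
}
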