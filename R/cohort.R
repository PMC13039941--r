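#' Assign a risk tier from a baseline risk percentile
#'
#' Percentile 1 is the riskiest. The tier cut points are fixed at the
#' operational convention: percentile 1 is "high", 2--24 "moderate",
#' 25--100 "low".
#'
#' @param percentile integer vector of risk percentiles in \[1, 100\].
#' @return factor with levels `high`, `moderate`, `low`.
#' @examples
#' assign_tier(c(1, 24, 25, 100))
#' @export
assign_tier <- function(percentile) {
  if (length(percentile) == 0L) {
    return(factor(character(), levels = c("high", "moderate", "low")))
  }
  bad <- !is.numeric(percentile) | is.na(percentile) |
    percentile != as.integer(percentile) |
    percentile < 1 | percentile > 100
  if (any(bad)) {
    stop("percentile must be an integer in [1,100]; offending value(s): ",
         paste(utils::head(percentile[bad], 5L), collapse = ", "))
  }
  tier <- ifelse(percentile == 1, "high",
                 ifelse(percentile <= 24, "moderate", "low"))
  factor(tier, levels = c("high", "moderate", "low"))
}

#' Restrict notes to a pre-index window
#'
#' Keeps the notes written between `min_days` and `max_days` whole calendar
#' days before the patient's index date (the case death date, or the matched
#' end-date for controls), inclusive at both ends. Notes closer to the index
#' date than `min_days` are dropped to guard against post-hoc documentation
#' contaminating the corpus; notes after the index date are likewise dropped.
#'
#' @param notes data.frame with columns `note_id`, `patient_id`, `note_date`
#'   (`Date` or ISO-8601 string), `text`.
#' @param cohort cohort table (see [read_cohort()]) with `patient_id` and
#'   `index_date`.
#' @param min_days,max_days inclusive window bounds in days before index.
#' @return the retained subset of `notes`, with a `days_before` column added.
#' @export
filter_window <- function(notes, cohort, min_days = 5L, max_days = 30L) {
  stopifnot(min_days < max_days, min_days >= 0)
  unknown <- setdiff(notes$patient_id, cohort$patient_id)
  if (length(unknown) > 0L) {
    stop("notes reference unknown patient_id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  idx <- as.Date(cohort$index_date)[match(notes$patient_id, cohort$patient_id)]
  days_before <- as.integer(idx - as.Date(notes$note_date))
  keep <- days_before >= min_days & days_before <= max_days
  out <- notes[keep, , drop = FALSE]
  out$days_before <- days_before[keep]
  rownames(out) <- NULL
  out
}

#' Match controls to cases on risk percentile
#'
#' Greedy 1:k matching without replacement: cases are visited in a seeded
#' random order and each draws up to `k` controls sharing its exact risk
#' percentile (and facility, when a `facility` column is present in both
#' tables). Matched controls inherit the case's index date, so case and
#' control note windows cover equivalent periods. Cases that cannot fill
#' their quota keep whatever was found and are flagged.
#'
#' @param cases data.frame of cases (`patient_id`, `percentile`, `index_date`,
#'   optional `facility`, covariates).
#' @param pool data.frame of candidate controls with the same columns.
#' @param k controls per case.
#' @param seed integer seed for the matching order.
#' @return a cohort data.frame stacking cases and their matched controls with
#'   columns `status` (`"case"`/`"control"`), `match_group`, `tier`, and a
#'   logical `match_incomplete` flag on every member of a short group.
#' @export
match_controls <- function(cases, pool, k = 5L, seed = 1L) {
  stopifnot(k >= 1L)
  if (nrow(pool) == 0L) warning("empty control pool; no controls matched")
  use_fac <- "facility" %in% names(cases) && "facility" %in% names(pool)
  rng <- local({ set.seed(seed); sample.int(nrow(cases)) })
  taken <- rep(FALSE, nrow(pool))
  rows <- vector("list", nrow(cases))
  for (i in rng) {
    ok <- !taken & pool$percentile == cases$percentile[i]
    if (use_fac) ok <- ok & pool$facility == cases$facility[i]
    pick <- which(ok)
    if (length(pick) > k) pick <- pick[seq_len(k)]
    taken[pick] <- TRUE
    if (length(pick) < k) {
      warning(sprintf("case %s: only %d of %d controls matched",
                      cases$patient_id[i], length(pick), k))
    }
    grp <- sprintf("mg%05d", i)
    ca <- cases[i, , drop = FALSE]
    ca$status <- "case"
    co <- pool[pick, , drop = FALSE]
    if (nrow(co) > 0L) {
      co$status <- "control"
      co$index_date <- ca$index_date  # follow-up period mirrors the case's
    }
    both <- rbind(ca[intersect(names(ca), names(co))],
                  if (nrow(co)) co[intersect(names(ca), names(co))])
    both$status <- c("case", rep("control", nrow(co)))
    both$match_group <- grp
    both$match_incomplete <- length(pick) < k
    rows[[i]] <- both
  }
  out <- do.call(rbind, rows)
  out$tier <- assign_tier(out$percentile)
  rownames(out) <- NULL
  out
}

#' Standardized mean difference between cases and controls
#'
#' SMD = |mean_case - mean_control| / sqrt((var_case + var_control) / 2).
#' Binary covariates (all values in \{0, 1\}) use proportions with variance
#' p(1 - p). Conventional magnitude labels use the 0.2 / 0.5 / 0.8 cut
#' points.
#'
#' @param cohort cohort data.frame with a `status` column.
#' @param covariate name of the covariate column.
#' @return list with `smd` (numeric) and `label` (`"negligible"`, `"small"`,
#'   `"medium"`, `"large"`).
#' @export
compute_smd <- function(cohort, covariate) {
  stopifnot(covariate %in% names(cohort))
  x <- cohort[[covariate]]
  a <- x[cohort$status == "case"]
  b <- x[cohort$status == "control"]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("covariate '", covariate, "' needs >= 2 non-missing values per arm")
  }
  binary <- all(x %in% c(0, 1, NA))
  if (binary) {
    pa <- mean(a); pb <- mean(b)
    va <- pa * (1 - pa); vb <- pb * (1 - pb)
    diff <- abs(pa - pb)
  } else {
    va <- stats::var(a); vb <- stats::var(b)
    diff <- abs(mean(a) - mean(b))
  }
  pooled <- sqrt((va + vb) / 2)
  if (pooled == 0) {
    if (diff == 0) {
      smd <- 0
    } else {
      warning("zero pooled sd with unequal means for '", covariate, "'")
      smd <- Inf
    }
  } else {
    smd <- diff / pooled
  }
  label <- if (smd < 0.2) "negligible" else if (smd < 0.5) "small" else
    if (smd < 0.8) "medium" else "large"
  list(smd = smd, label = label)
}

#' Read a patient cohort table from CSV
#'
#' Expected header: `patient_id,status,index_date,percentile` plus optional
#' `facility`, `match_group` and covariate columns; dates ISO-8601. A `tier`
#' column is derived from the percentile.
#'
#' @param path CSV file path.
#' @return data.frame with `index_date` parsed as `Date` and a `tier` factor.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "status", "index_date", "percentile")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort file missing column(s): ",
                         paste(miss, collapse = ", "))
  df$index_date <- as.Date(df$index_date)
  df$tier <- assign_tier(df$percentile)
  df
}

#' Write a cohort table to CSV
#' @param cohort cohort data.frame.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$index_date <- format(as.Date(out$index_date))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read clinical notes from JSON-Lines
#'
#' One JSON object per line with keys `note_id`, `patient_id`, `note_date`
#' (ISO-8601) and `text`.
#'
#' @param path JSONL file path.
#' @return data.frame of notes with `note_date` parsed as `Date`.
#' @export
read_notes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(
    note_id = vapply(recs, `[[`, "", "note_id"),
    patient_id = vapply(recs, `[[`, "", "patient_id"),
    note_date = as.Date(vapply(recs, `[[`, "", "note_date")),
    text = vapply(recs, `[[`, "", "text"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$note_id)) stop("duplicate note_id in ", path)
  df
}

#' Write clinical notes to JSON-Lines
#' @param notes notes data.frame.
#' @param path output path.
#' @export
write_notes <- function(notes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    writeLines(jsonlite::toJSON(list(
      note_id = notes$note_id[i],
      patient_id = notes$patient_id[i],
      note_date = format(as.Date(notes$note_date[i])),
      text = notes$text[i]
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}
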