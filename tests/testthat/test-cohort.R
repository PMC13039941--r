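test_that("tier assignment follows the 1 / 2-24 / 25-100 cut points", {
  expect_equal(as.character(assign_tier(1L)), "high")
  expect_equal(as.character(assign_tier(2L)), "moderate")
  expect_equal(as.character(assign_tier(24L)), "moderate")
  expect_equal(as.character(assign_tier(25L)), "low")
  expect_equal(as.character(assign_tier(100L)), "low")
})

test_that("tier assignment partitions [1,100] exactly and rejects bad input", {
  tiers <- assign_tier(1:100)
  expect_false(anyNA(tiers))
  expect_equal(as.integer(table(tiers)), c(1L, 23L, 76L))
  expect_error(assign_tier(0L), "offending")
  expect_error(assign_tier(101L), "offending")
  expect_error(assign_tier(10.5), "offending")
})

test_that("window filter keeps [5,30] days before index, inclusive", {
  cohort <- tiny_cohort(1L, 0L)
  notes <- notes_at_days(c(-2L, 0L, 3L, 4L, 5L, 15L, 30L, 31L, 60L))
  kept <- filter_window(notes, cohort)
  expect_setequal(kept$days_before, c(5L, 15L, 30L))
  # boundary day 5 retained, 0-4 dropped as near-index contamination guard
  expect_true(5L %in% kept$days_before)
  expect_false(any(kept$days_before < 5L))
})

test_that("window filtering is idempotent and order-independent", {
  cohort <- tiny_cohort(1L, 0L)
  notes <- notes_at_days(sample(c(0:40, -3:-1)))
  once <- filter_window(notes, cohort)
  twice <- filter_window(once[names(notes)], cohort)
  expect_equal(sort(once$note_id), sort(twice$note_id))
  shuffled <- notes[rev(seq_len(nrow(notes))), ]
  expect_setequal(filter_window(shuffled, cohort)$note_id, once$note_id)
})

test_that("window filter rejects notes from unknown patients", {
  cohort <- tiny_cohort(1L, 0L)
  notes <- notes_at_days(10L, patient_id = "ghost")
  expect_error(filter_window(notes, cohort), "unknown patient_id")
})

test_that("matching yields exactly k controls per case with ample pool", {
  set.seed(7)
  cases <- data.frame(patient_id = sprintf("c%02d", 1:10),
                      percentile = sample(1:100, 10),
                      index_date = as.Date("2017-06-01"),
                      stringsAsFactors = FALSE)
  pool <- data.frame(patient_id = sprintf("k%04d", 1:1000),
                     percentile = rep(cases$percentile, each = 100),
                     index_date = as.Date("2016-01-01"),
                     stringsAsFactors = FALSE)
  cohort <- match_controls(cases, pool, k = 5L, seed = 1L)
  expect_equal(sum(cohort$status == "control"), 50L)
  expect_equal(length(unique(cohort$match_group)), 10L)
  sizes <- table(cohort$match_group)
  expect_true(all(sizes == 6L))
  # match groups are percentile-homogeneous and share the case's index date
  for (g in unique(cohort$match_group)) {
    sub <- cohort[cohort$match_group == g, ]
    expect_equal(length(unique(sub$percentile)), 1L)
    expect_equal(length(unique(sub$index_date)), 1L)
    expect_equal(sum(sub$status == "case"), 1L)
  }
  # without replacement: each control used once
  ctrl <- cohort$patient_id[cohort$status == "control"]
  expect_false(anyDuplicated(ctrl) > 0)
})

test_that("short match groups are kept and flagged", {
  cases <- data.frame(patient_id = "c01", percentile = 7L,
                      index_date = as.Date("2017-06-01"),
                      stringsAsFactors = FALSE)
  pool <- data.frame(patient_id = "k01", percentile = 50L,
                     index_date = as.Date("2016-01-01"),
                     stringsAsFactors = FALSE)
  expect_warning(cohort <- match_controls(cases, pool, k = 5L), "only 0 of 5")
  expect_equal(nrow(cohort), 1L)
  expect_true(all(cohort$match_incomplete))
})

test_that("k=1 with an exact-copy pool forces a case-control bijection", {
  cases <- data.frame(patient_id = sprintf("c%02d", 1:8),
                      percentile = sample(1:100, 8),
                      index_date = as.Date("2017-06-01"),
                      stringsAsFactors = FALSE)
  pool <- cases
  pool$patient_id <- sub("c", "k", pool$patient_id)
  cohort <- suppressWarnings(match_controls(cases, pool, k = 1L, seed = 2L))
  ctrl <- cohort[cohort$status == "control", ]
  expect_equal(nrow(ctrl), 8L)
  for (g in unique(cohort$match_group)) {
    sub <- cohort[cohort$match_group == g, ]
    expect_equal(sub$percentile[1], sub$percentile[2])
  }
})

test_that("SMD matches the hand-computed pooled-variance formula", {
  cohort <- data.frame(status = rep(c("case", "control"), each = 3L),
                       x = c(1, 2, 3, 2, 3, 4))
  # |2-3| / sqrt((1+1)/2) = 1.0
  res <- compute_smd(cohort, "x")
  expect_equal(res$smd, 1.0)
  expect_equal(res$label, "large")
})

test_that("SMD is symmetric in arms and invariant to affine rescaling", {
  set.seed(11)
  cohort <- data.frame(status = rep(c("case", "control"), each = 30L),
                       x = c(rnorm(30, 1), rnorm(30, 1.4)))
  a <- compute_smd(cohort, "x")$smd
  flipped <- cohort
  flipped$status <- ifelse(cohort$status == "case", "control", "case")
  expect_equal(compute_smd(flipped, "x")$smd, a)
  scaled <- cohort
  scaled$x <- 3.7 * cohort$x - 12
  expect_equal(compute_smd(scaled, "x")$smd, a, tolerance = 1e-12)
})

test_that("SMD handles binary covariates and degenerate spreads", {
  cohort <- data.frame(status = rep(c("case", "control"), each = 10L),
                       b = c(rep(c(0, 1), 5), rep(c(0, 1), 5)))
  expect_equal(compute_smd(cohort, "b")$smd, 0)
  same <- data.frame(status = rep(c("case", "control"), each = 3L),
                     x = rep(2, 6))
  expect_equal(compute_smd(same, "x")$smd, 0)
  apart <- data.frame(status = rep(c("case", "control"), each = 3L),
                      x = rep(c(1, 2), each = 3L))
  expect_warning(res <- compute_smd(apart, "x"), "zero pooled sd")
  expect_true(is.infinite(res$smd))
})

test_that("cohort and notes round-trip through CSV / JSONL", {
  corp <- generate_corpus(generator_spec(n_cases = 3L, seed = 5L))
  dir <- withr::local_tempdir()
  write_cohort(corp$cohort, file.path(dir, "cohort.csv"))
  back <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(back$patient_id, corp$cohort$patient_id)
  expect_equal(back$percentile, corp$cohort$percentile)
  expect_equal(as.character(back$tier), as.character(corp$cohort$tier))
  expect_equal(back$index_date, as.Date(corp$cohort$index_date))
  write_notes(corp$notes, file.path(dir, "notes.jsonl"))
  nback <- read_notes(file.path(dir, "notes.jsonl"))
  expect_equal(nback$note_id, corp$notes$note_id)
  expect_equal(nback$text, corp$notes$text)
  expect_equal(nback$note_date, as.Date(corp$notes$note_date))
})
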