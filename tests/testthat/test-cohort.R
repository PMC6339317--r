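mini_cases <- function() {
  tibble::tibble(
    doc_id = paste0("d", 1:4),
    patient_id = paste0("p", 1:4),
    case_id = paste0("c", 1:4),
    admission_date = as.Date("2015-01-01"),
    discharge_date = as.Date(c("2015-01-10", "2016-06-01", "2015-03-01",
                               "2015-05-01")),
    age_years = c(70L, 45L, 101L, 80L),
    sex = c("f", "m", "f", "m"),
    icd_codes = list(c("I48.1", "I10"), c("I48.0"), c("I48.9"),
                     c("I48.0", "I05.1"))
  )
}

test_that("cohort criteria combine include, exclude, date and age", {
  docs <- mini_cases()
  flt <- cohort_filter(include_icd = "I48",
                       exclude_icd = c("I05", "I06", "I07", "I08", "I09"),
                       date_start = "2015-01-01", date_end = "2016-01-01",
                       age_min = 30, age_max = 100)
  kept <- apply_cohort_filter(docs, flt)
  # d2 out of date range, d3 over age, d4 valvular exclusion
  expect_identical(kept$doc_id, "d1")
})

test_that("an empty filter is the identity", {
  docs <- mini_cases()
  expect_identical(apply_cohort_filter(docs, cohort_filter())$doc_id,
                   docs$doc_id)
})

test_that("malformed ICD prefixes are rejected at construction", {
  expect_error(cohort_filter(include_icd = "48I"), "malformed ICD")
})

test_that("adding an exclude prefix never grows the cohort", {
  docs <- mini_cases()
  base <- apply_cohort_filter(docs, cohort_filter(include_icd = "I48"))
  for (ex in list("I05", c("I05", "I10"), c("I05", "I10", "I48"))) {
    sub <- apply_cohort_filter(docs, cohort_filter(include_icd = "I48",
                                                   exclude_icd = ex))
    expect_lte(nrow(sub), nrow(base))
    expect_true(all(sub$doc_id %in% base$doc_id))
  }
})

test_that("filtering matches an independent linear re-check", {
  gc <- generate_corpus(gen_config(seed = 51, n_docs = 100))
  docs <- gc$docs
  flt <- cohort_filter(include_icd = c("I48", "I10"),
                       exclude_icd = "I05",
                       date_start = "2008-01-01",
                       date_end = "2016-01-01",
                       age_min = 40, age_max = 85)
  kept <- apply_cohort_filter(docs, flt)$doc_id
  # oracle: per-case loop re-applying each criterion separately
  want <- character(0)
  for (i in seq_len(nrow(docs))) {
    codes <- docs$icd_codes[[i]]
    inc <- any(substr(codes, 1, 3) %in% c("I48", "I10"))
    exc <- any(substr(codes, 1, 3) == "I05")
    dd <- docs$discharge_date[i]
    in_date <- dd >= as.Date("2008-01-01") && dd < as.Date("2016-01-01")
    in_age <- docs$age_years[i] >= 40 && docs$age_years[i] <= 85
    if (inc && !exc && in_date && in_age) want <- c(want, docs$doc_id[i])
  }
  expect_identical(kept, want)
})

test_that("trend rows satisfy the percentage invariant", {
  cfg <- gen_config(
    seed = 52, n_docs = 120,
    periods = tibble::tibble(
      label = c("P1", "P2", "P3"),
      start = as.Date(c("2006-01-01", "2010-01-01", "2014-01-01")),
      end = as.Date(c("2010-01-01", "2014-01-01", "2018-01-01"))
    ),
    group_prevalence = c(C07 = 0.40, B01AF01 = 0.15)
  )
  gc <- generate_corpus(cfg)
  built <- build_corpus_index(gc$docs)
  meds <- extract_medications(built$index, default_drug_db())
  tr <- drug_prevalence_trend(
    gc$docs, meds,
    tibble::tibble(label = c("Beta blockers", "Rivaroxaban"),
                   atc_prefix = c("C07", "B01AF01")),
    cfg$periods
  )
  expect_identical(nrow(tr), 6L)
  expect_true(all(tr$percent >= 0 & tr$percent <= 100))
  expect_true(all(tr$n_with <= tr$n_cases))
  expect_equal(tr$percent, 100 * tr$n_with / tr$n_cases)
})

test_that("a case with two drugs of one group counts once", {
  docs <- tibble::tibble(
    doc_id = "d1", patient_id = "p1", case_id = "c1",
    admission_date = as.Date("2015-01-01"),
    discharge_date = as.Date("2015-01-05"),
    age_years = 70L, sex = "f", icd_codes = list("I48"),
    text = "Medikation:\nConcor 5mg 1-0-0, Metoprolol 47,5mg 0-0-1"
  )
  built <- build_corpus_index(docs)
  meds <- extract_medications(built$index, default_drug_db())
  expect_identical(nrow(meds), 2L)
  tr <- drug_prevalence_trend(
    docs, meds,
    tibble::tibble(label = "Beta blockers", atc_prefix = "C07"),
    tibble::tibble(label = "all", start = as.Date("2015-01-01"),
                   end = as.Date("2016-01-01"))
  )
  expect_identical(tr$n_with, 1L)
  expect_equal(tr$percent, 100)
})

test_that("an empty period reports zero with a flag", {
  docs <- mini_cases()
  docs$text <- "Medikation:\nConcor 5mg 1-0-0"
  built <- build_corpus_index(docs)
  meds <- extract_medications(built$index, default_drug_db())
  tr <- drug_prevalence_trend(
    docs, meds,
    tibble::tibble(label = "Beta blockers", atc_prefix = "C07"),
    tibble::tibble(label = "empty", start = as.Date("1990-01-01"),
                   end = as.Date("1991-01-01"))
  )
  expect_identical(tr$n_cases, 0L)
  expect_equal(tr$percent, 0)
  expect_true(tr$undefined)
})

test_that("overlapping periods warn", {
  docs <- mini_cases()
  docs$text <- ""
  built <- build_corpus_index(docs)
  meds <- extract_medications(built$index, default_drug_db())
  expect_warning(
    drug_prevalence_trend(
      docs, meds, tibble::tibble(label = "BB", atc_prefix = "C07"),
      tibble::tibble(label = c("a", "b"),
                     start = as.Date(c("2015-01-01", "2015-06-01")),
                     end = as.Date(c("2016-01-01", "2016-06-01")))
    ),
    "overlap"
  )
})

test_that("numeric concept values are the first number after the concept", {
  docs <- tibble::tibble(
    doc_id = "d1",
    text = "Befunde:\nRR 135/80 mmHg\nRR 160/95 mmHg\nPuls 72"
  )
  built <- build_corpus_index(docs, include = "lines")
  vals <- extract_numeric_concept(built$index, "RR", window = 3)
  expect_equal(sort(vals$value), c(135, 160))
})

test_that("value binning is exhaustive, exclusive and percentages sum", {
  edges <- c(130, 140, 150, 160)
  g <- group_values(c(129.9, 130, 139.9, 145, 159.9, 200), edges)
  expect_identical(g$bin[1], "<130")
  expect_identical(g$n, c(1L, 2L, 1L, 1L, 1L))
  expect_equal(sum(g$percent), 100)
  # boundary value lands in the right-closed side of no bin twice
  expect_identical(sum(g$n), 6L)
})

test_that("empty values bin to zero rows with a warning", {
  expect_warning(g <- group_values(numeric(0), c(130, 140)), "no values")
  expect_true(all(g$n == 0L))
})
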