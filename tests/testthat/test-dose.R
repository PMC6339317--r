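parse_sentence_dose <- function(text, drug_tokens = 1L) {
  tok <- tokenize(text)
  parse_dose_instruction(tok, drug_end = drug_tokens - 1L)
}

test_that("strength and dosing pattern parse from worked instructions", {
  d <- parse_sentence_dose("Delix 5mg 1/2-0-1/2")
  expect_equal(d$strength, 5)
  expect_identical(d$unit, "mg")
  expect_equal(d$pattern[[1]], c(0.5, 0, 0.5))
  expect_equal(d$daily_units, 1)
  expect_equal(d$daily_dose, 5)

  d2 <- parse_sentence_dose("Delix 5mg 1-0-1")
  expect_equal(d2$daily_dose, 10)
})

test_that("a parenthetical supplement is skipped up to the pattern gap", {
  d <- parse_sentence_dose("Concor 5 mg (bei Bedarf) 1 – 0 – 0 – 1")
  expect_equal(d$strength, 5)
  expect_equal(d$pattern[[1]], c(1, 0, 0, 1))
  expect_equal(d$daily_units, 2)
  expect_equal(d$daily_dose, 10)
})

test_that("a bare drug name has both components absent", {
  d <- parse_sentence_dose("Eunerpan")
  expect_true(is.na(d$strength))
  expect_null(d$pattern[[1]])
  expect_true(is.na(d$daily_dose))
})

test_that("strength without unit is not parsed and large numbers are not schedules", {
  # a strength written in pattern notation is a known failure notation,
  # not a schedule of 150 units
  d <- parse_sentence_dose("Pradaxa 150-0-150 mg")
  expect_true(is.na(d$daily_units))
  d2 <- parse_sentence_dose("Mono-Mack 20 1-1-0", drug_tokens = 2L)
  expect_true(is.na(d2$strength))
  expect_equal(d2$pattern[[1]], c(1, 1, 0))
})

test_that("decimal-comma strengths parse", {
  d <- parse_sentence_dose("Esidrix 12,5 mg 1-0-0")
  expect_equal(d$strength, 12.5)
  expect_equal(d$daily_dose, 12.5)
})

test_that("daily dose is strength times the schedule sum", {
  expect_equal(compute_daily_dose(5, c(1, 0, 1)), 10)
  expect_equal(compute_daily_dose(5, c(0, 0, 0)), 0)
  expect_equal(compute_daily_dose(110, c(1, 0, 1)), 220)
  expect_equal(compute_daily_dose(5, c(1, 0, 0, 1)), 10)
  expect_error(compute_daily_dose(5, c(1, 0)), "3 or 4")
  expect_error(compute_daily_dose(5, c(1, 0, 0, 1, 0)), "3 or 4")
})

test_that("daily dose is linear in strength and additive in the pattern", {
  set.seed(5)
  for (i in 1:30) {
    s <- runif(1, 0.5, 200)
    d <- sample(c(0, 0.25, 0.5, 1, 2), 3, TRUE)
    expect_equal(compute_daily_dose(2 * s, d), 2 * compute_daily_dose(s, d))
    e <- sample(c(0, 0.5, 1), 3, TRUE)
    expect_equal(compute_daily_dose(s, d) + compute_daily_dose(s, e),
                 s * (sum(d) + sum(e)))
  }
})

test_that("dose-query expansion errors on an unknown daily-unit key", {
  expect_error(expand_dose_query("Delix", 5, 7), "no dosing patterns")
  expect_error(expand_dose_query("Delix", 5, 1, catalog = list()),
               "no dosing patterns")
})

test_that("the default catalog covers the observed daily-unit totals", {
  cat <- default_pattern_catalog()
  expect_setequal(names(cat),
                  c("0.25", "0.5", "1", "1.5", "2", "3", "4"))
  for (u in names(cat)) {
    sums <- vapply(cat[[u]], sum, numeric(1))
    expect_true(all(abs(sums - as.numeric(u)) < 1e-9))
  }
})

test_that("dose-query hits agree with parsed daily doses", {
  # the two extraction pathways (query expansion vs sig parsing) must
  # agree on every hit
  gc <- generate_corpus(gen_config(seed = 41, n_docs = 80))
  built <- build_corpus_index(gc$docs)
  ix <- built$index
  db <- default_drug_db()
  meds <- extract_medications(ix, db)
  for (u in c(0.5, 1, 2)) {
    q <- expand_dose_query("Delix", 5, u)
    hits <- execute(q, ix)
    if (nrow(hits) == 0) next
    parsed <- meds[meds$sentence_id %in% hits$sentence_id &
                     meds$canonical == "Delix", ]
    expect_true(all(abs(parsed$daily_units - u) < 1e-9))
    expect_true(all(abs(parsed$strength - 5) < 1e-9))
  }
})

test_that("published dose distributions give the printed averages", {
  expect_equal(round(average_daily_dose(eliquis_distribution()), 1), 7.4)
  expect_equal(round(average_daily_dose(pradaxa_distribution()), 1),
               232.3)
  # the printed value rounds the cells; recomputation lands within 0.1
  expect_lt(abs(average_daily_dose(xarelto_distribution()) - 19.3), 0.11)
})

test_that("a single-cell distribution averages to its own dose", {
  one <- tibble::tibble(daily_units = 2, strength = 10, proportion = 1)
  expect_equal(average_daily_dose(one), 20)
  expect_error(
    average_daily_dose(tibble::tibble(daily_units = numeric(0),
                                      strength = numeric(0),
                                      proportion = numeric(0))),
    "empty"
  )
})

test_that("the average lies between the extreme cell doses", {
  set.seed(6)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    dist <- tibble::tibble(
      daily_units = sample(c(0.5, 1, 2, 3), k, TRUE),
      strength = sample(c(5, 10, 110, 150), k, TRUE),
      proportion = as.numeric(stats::rmultinom(1, 100, rep(1, k))) / 100
    )
    dist <- dist[dist$proportion > 0, ]
    avg <- average_daily_dose(dist)
    doses <- dist$daily_units * dist$strength
    expect_gte(avg, min(doses) - 1e-9)
    expect_lte(avg, max(doses) + 1e-9)
  }
})

test_that("aggregation excludes discontinued instructions", {
  doses <- tibble::tibble(
    daily_units = c(1, 1, 2), strength = c(20, 20, 15),
    unit = "mg", discontinued = c(FALSE, TRUE, FALSE)
  )
  dist <- aggregate_dose_distribution(doses, drug = "Xarelto")
  expect_identical(sum(dist$n), 2L)
  expect_equal(sum(dist$proportion), 1)
  expect_identical(attr(dist, "drug"), "Xarelto")
})

test_that("an aggregated synthetic distribution matches its instructions", {
  gc <- generate_corpus(gen_config(seed = 43, n_docs = 120))
  built <- build_corpus_index(gc$docs)
  meds <- extract_medications(built$index, default_drug_db())
  xar <- meds[meds$canonical == "Xarelto", ]
  dist <- aggregate_dose_distribution(xar, drug = "Xarelto")
  expect_equal(sum(dist$proportion), 1)
  gold_xar <- gc$gold[gc$gold$canonical == "Xarelto" &
                        !gc$gold$discontinued & !gc$gold$historical &
                        !is.na(gc$gold$daily_dose), ]
  expect_equal(
    sort(rep(dist$daily_units * dist$strength, dist$n)),
    sort(gold_xar$daily_dose)
  )
})
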