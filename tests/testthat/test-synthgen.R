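test_that("generation is deterministic given the seed", {
  cfg <- gen_config(seed = 61, n_docs = 15, p_misspell = 0.2,
                    p_abbreviation = 0.1)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$docs$text, b$docs$text)
  expect_identical(a$gold, b$gold)
  c <- generate_corpus(gen_config(seed = 62, n_docs = 15))
  expect_false(identical(a$docs$text, c$docs$text))
})

test_that("configuration probabilities and distributions are validated", {
  expect_error(gen_config(p_strength = 1.2), "probs")
  expect_error(gen_config(daily_units_dist = c("1" = 0.5, "2" = 0.4)),
               "sum to 1")
})

test_that("without corruption every surface form is a lexicon term", {
  gc <- generate_corpus(gen_config(seed = 63, n_docs = 40))
  db <- default_drug_db()
  terms <- tolower(c(
    vapply(db$processed, paste, "", collapse = " "),
    unlist(lapply(db$alt, function(a) {
      vapply(a, paste, "", collapse = " ")
    }))
  ))
  expect_true(all(tolower(gc$gold$surface_name) %in% terms))
  expect_false(any(gc$gold$misspelled))
  expect_false(any(gc$gold$abbreviated))
})

test_that("gold spans point at the drug name in the document text", {
  gc <- generate_corpus(gen_config(seed = 64, n_docs = 25,
                                   p_misspell = 0.15))
  txt <- stats::setNames(gc$docs$text, gc$docs$doc_id)
  for (i in seq_len(nrow(gc$gold))) {
    expect_identical(
      substring(txt[[gc$gold$doc_id[i]]], gc$gold$start[i] + 1,
                gc$gold$end[i]),
      gc$gold$surface_name[i]
    )
  }
})

test_that("daily-unit frequencies track the configured distribution", {
  cfg <- gen_config(seed = 65, n_docs = 1500)
  gc <- generate_corpus(cfg)
  du <- gc$gold$daily_units[!is.na(gc$gold$daily_units)]
  expect_gt(length(du), 5000)
  freq <- table(factor(du, levels = names(cfg$daily_units_dist))) /
    length(du)
  for (u in names(cfg$daily_units_dist)) {
    expect_lt(abs(freq[[u]] - cfg$daily_units_dist[[u]]), 0.02)
  }
})

test_that("strength and instruction presence follow the configured rates", {
  gc <- generate_corpus(gen_config(seed = 66, n_docs = 400))
  g <- gc$gold
  expect_lt(abs(mean(!is.na(g$strength)) - 0.90), 0.03)
  expect_lt(abs(mean(!is.na(g$daily_units)) - 0.92), 0.03)
  expect_lt(abs(mean(g$discontinued) - 0.05), 0.02)
})

test_that("name corruption is a single edit of the requested kind", {
  set.seed(77)
  for (mode in c("substitution", "insertion", "deletion",
                 "transposition")) {
    for (nm in c("Ramipril", "Fraxiparin", "Euphylong")) {
      out <- corrupt_name(nm, mode)
      expect_false(identical(out, nm))
      expect_identical(dl_distance(nm, out), 1L)
      expect_identical(osa_oracle(nm, out), 1L)
    }
  }
  # unspecified mode still yields one edit
  for (i in 1:20) {
    out <- corrupt_name("Repaglinid")
    expect_identical(dl_distance("Repaglinid", out), 1L)
  }
  expect_error(corrupt_name("ACC"), "too short")
})

test_that("a perfect prediction scores ones and deletions lower recall", {
  gc <- generate_corpus(gen_config(seed = 67, n_docs = 30))
  gold <- gc$gold[!gc$gold$discontinued & !gc$gold$historical, ]
  pred <- tibble::tibble(
    doc_id = gold$doc_id, canonical = gold$canonical,
    doc_start = gold$start, doc_end = gold$end
  )
  perfect <- tidy(evaluate_extraction(pred, gold))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$F1, 1)

  n <- nrow(pred)
  k <- 7L
  dropped <- tidy(evaluate_extraction(pred[seq_len(n - k), ], gold))
  expect_equal(dropped$recall, (n - k) / n)
  expect_equal(dropped$precision, 1)

  empty <- tidy(evaluate_extraction(pred[0, ], gold))
  expect_equal(empty$precision, 0)
  expect_equal(empty$recall, 0)
  expect_equal(empty$F1, 0)
})

test_that("each gold record matches at most one prediction", {
  gold <- tibble::tibble(doc_id = "d1", canonical = "Delix",
                         start = 10L, end = 15L)
  pred <- tibble::tibble(doc_id = "d1", canonical = "Delix",
                         doc_start = c(10L, 10L), doc_end = c(15L, 15L))
  m <- tidy(evaluate_extraction(pred, gold))
  expect_identical(m$TP, 1L)
  expect_identical(m$FP, 1L)
  expect_identical(m$FN, 0L)
})

test_that("an empty lexicon is rejected", {
  expect_error(generate_corpus(gen_config(), default_drug_db()[0, ]),
               "empty drug lexicon")
})

test_that("generated corpora survive a JSONL round trip", {
  gc <- generate_corpus(gen_config(seed = 68, n_docs = 8))
  p <- tempfile(fileext = ".jsonl")
  write_corpus_jsonl(gc$docs, p)
  back <- read_corpus_jsonl(p)
  expect_identical(back$doc_id, gc$docs$doc_id)
  expect_identical(back$text, gc$docs$text)
  expect_identical(back$icd_codes, gc$docs$icd_codes)
  expect_identical(back$discharge_date, gc$docs$discharge_date)
})
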