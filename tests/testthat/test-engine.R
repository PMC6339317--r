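test_that("edit distances reproduce the misspelling examples", {
  product <- c("Ibuhexal", "Cordarex", "Warfarin", "Euphylong",
               "Repaglinid", "Ramipril", "Repaglinid")
  misspell <- c("Ibohexal", "Kordarex", "Wafarin", "Euphyllong",
                "Repagilnid", "Rampiril", "Repagilid")
  expect_identical(dl_distance(product, misspell),
                   c(1L, 1L, 1L, 1L, 1L, 1L, 2L))
})

test_that("the distance is a symmetric metric bounded by length", {
  set.seed(99)
  for (i in 1:50) {
    a <- paste(sample(letters[1:6], sample(0:12, 1), TRUE), collapse = "")
    b <- paste(sample(letters[1:6], sample(0:12, 1), TRUE), collapse = "")
    d <- dl_distance(a, b)
    expect_identical(d, dl_distance(b, a))
    expect_lte(d, max(nchar(a), nchar(b)))
    expect_identical(d == 0L, a == b)
    # never exceeds plain Levenshtein (transposition only helps)
    expect_lte(d, as.integer(utils::adist(a, b)))
  }
})

test_that("the distance agrees with the exhaustive DP oracle", {
  set.seed(7)
  for (i in 1:400) {
    a <- paste(sample(letters[1:5], sample(1:12, 1), TRUE), collapse = "")
    b <- paste(sample(letters[1:5], sample(1:12, 1), TRUE), collapse = "")
    expect_identical(dl_distance(a, b), osa_oracle(a, b))
  }
})

test_that("fuzzy expansion finds close vocabulary tokens", {
  expect_identical(fuzzy_expand("Ibuhexal", c("ibohexal"), max_dist = 1),
                   "ibohexal")
  # the documented false-positive mode of short-distance matching
  expect_identical(fuzzy_expand("diabetes", c("diabetex"), max_dist = 1),
                   "diabetex")
  expect_identical(fuzzy_expand("anything", character(0)), character(0))
  # short tokens match exactly only
  expect_identical(fuzzy_expand("mack", c("mack", "mock")), "mack")
})

test_that("the exact match is always included", {
  vocab <- c("delix", "felix", "demix")
  expect_true("delix" %in% fuzzy_expand("Delix", vocab, max_dist = 1))
})

test_that("an index over the worked sentences has the expected vocabulary", {
  ix <- make_index(c("Delix 10mg 1-0-0", "Belok zok 1/2-0-0",
                     "Mono-Mack 20 1-1-0"))
  expect_setequal(ix$index$vocab,
                  c("delix", "10", "mg", "1", "0", "belok", "zok", "1/2",
                    "mono", "mack", "20"))
})

test_that("an empty corpus builds an empty index", {
  ix <- build_index(
    tibble::tibble(doc_id = character(0), sentence_id = character(0),
                   text = character(0)),
    tokenize_sentences(tibble::tibble(doc_id = character(0),
                                      sentence_id = character(0),
                                      text = character(0)))
  )
  expect_identical(length(ix$vocab), 0L)
  expect_identical(nrow(ix$postings), 0L)
})

test_that("duplicate sentence ids are rejected", {
  sents <- tibble::tibble(doc_id = "d", sentence_id = c("s1", "s1"),
                          text = c("a", "b"))
  expect_error(build_index(sents, tokenize_sentences(sents)),
               "duplicate sentence_id")
})

test_that("postings count equals total token count on synthetic text", {
  gc <- generate_corpus(gen_config(seed = 31, n_docs = 50))
  built <- build_corpus_index(gc$docs)
  expect_identical(nrow(built$index$postings), nrow(built$tokens))
})

test_that("proximity dose queries classify the worked snippets", {
  ix <- make_index(c("Delix 5mg 1-0-0", "Delix 5mg 1/2-0-1/2",
                     "Delix 5mg 1-0-1", "Delix 5mg 0-0-1/2",
                     "Delix 5 mg 0-1-1/2"))
  q <- expand_dose_query("Delix", 5, 1, catalog = table3_catalog())
  hits <- execute(q, ix$index)
  expect_setequal(hits$snippet,
                  c("Delix 5mg 1-0-0", "Delix 5mg 1/2-0-1/2"))
})

test_that("order-preserving numerics reject the permuted dosing pattern", {
  # same daily total, but the schedule tokens appear as 0 1 0; under the
  # printed two-disjunct expansion this snippet must not match
  ix <- make_index("Delix 5-mg 0 1 0")
  q <- query_near(c("Delix", "5", "1", "0", "0"), slop = 1)
  expect_identical(nrow(execute(q, ix$index)), 0L)
  # order-free word tokens still match around the numbers
  q2 <- query_near(c("mg", "Delix", "5"), slop = 0)
  expect_identical(nrow(execute(q2, ix$index)), 1L)
})

test_that("proximity never matches across sentence boundaries", {
  ix <- make_index(c("Delix 5mg", "1-0-0 Concor"))
  q <- query_near(c("Delix", "5", "1", "0", "0"), slop = 2)
  expect_identical(nrow(execute(q, ix$index)), 0L)
})

test_that("a contradiction returns no hits", {
  ix <- make_index(c("Delix 5mg 1-0-0", "Concor 5mg"))
  q <- query_and(query_term("delix"), query_not(query_term("delix")))
  expect_identical(nrow(execute(q, ix$index)), 0L)
})

test_that("boolean algebra laws hold on a small index", {
  ix <- make_index(c("Delix 5mg 1-0-0", "Concor 5mg 0-0-1",
                     "Esidrix 12,5 mg", "kein Delix"))
  q <- query_term("delix")
  expect_identical(execute(query_or(q, q), ix$index)$sentence_id,
                   execute(q, ix$index)$sentence_id)
  # NOT is the complement over the sentence universe
  ids <- ix$index$sentences$sentence_id
  not_ids <- execute(query_not(q), ix$index)$sentence_id
  expect_setequal(c(execute(q, ix$index)$sentence_id, not_ids), ids)
})

test_that("phrase hits are a subset of proximity hits", {
  ix <- make_index(c("Belok zok 1/2-0-0", "zok Belok", "Belok mg zok"))
  ph <- execute(query_phrase(c("Belok", "zok")), ix$index)$sentence_id
  nr <- execute(query_near(c("Belok", "zok"), slop = 1),
                ix$index)$sentence_id
  expect_true(all(ph %in% nr))
  expect_identical(ph, "s1")
  expect_setequal(nr, c("s1", "s2", "s3"))
})

test_that("context exclusion drops flagged sentences from hits", {
  ix <- make_index(c("Delix 5mg 1-0-0", "Delix abgesetzt"))
  all_hits <- execute(query_term("delix"), ix$index)
  expect_identical(nrow(all_hits), 2L)
  act <- execute(query_active(query_term("delix"),
                              exclude = "discontinued"), ix$index)
  expect_identical(act$snippet, "Delix 5mg 1-0-0")
})

test_that("query evaluation equals a brute-force sentence scan", {
  set.seed(123)
  n_corpora <- 60
  for (r in seq_len(n_corpora)) {
    texts <- random_corpus_texts(sample(3:14, 1))
    ix <- make_index(texts)
    osents <- oracle_sents_from_index(ix)
    queries <- list(
      query_term(sample(c("delix", "esidrix", "mg", "1"), 1)),
      query_fuzzy(sample(c("delix", "belix", "esidrix", "concur"), 1)),
      query_phrase(sample(c("delix", "mg", "1", "0"), 2)),
      query_near(sample(c("delix", "mg", "5", "1", "0"), 3),
                 slop = sample(0:2, 1)),
      query_regex("^es"),
      query_and(query_term("delix"), query_term("mg")),
      query_or(query_term("esidrix"), query_near(c("1", "0"), slop = 1)),
      query_not(query_term("mg")),
      query_active(query_term("delix"), exclude = "negated")
    )
    for (q in queries) {
      got <- execute(q, ix$index)$sentence_id
      want <- oracle_execute(q, osents)
      expect_setequal(got, want)
    }
  }
})

test_that("the query DSL parses into the expected trees", {
  q <- parse_query('~1Ibuhexal AND NOT "Aspirin forte"')
  expect_identical(q$kind, "and")
  expect_identical(q$children[[1]]$kind, "fuzzy")
  expect_identical(q$children[[1]]$max_dist, 1L)
  expect_identical(q$children[[2]]$kind, "not")
  expect_identical(q$children[[2]]$child$tokens, c("Aspirin", "forte"))

  q2 <- parse_query("near/1(Delix 5 1 0 0) -negated -discontinued")
  expect_identical(q2$kind, "active")
  expect_setequal(q2$exclude, c("negated", "discontinued"))
  expect_identical(q2$child$kind, "near")
  expect_identical(q2$child$slop, 1L)

  q3 <- parse_query("(a OR b) AND c")
  expect_identical(q3$kind, "and")
  expect_identical(q3$children[[1]]$kind, "or")
  expect_error(parse_query(""), "empty query")
})

test_that("parsed DSL queries execute like hand-built ones", {
  ix <- make_index(c("Delix 5mg 1-0-0", "Ibohexal 400mg", "kein Delix"))
  expect_identical(
    execute(parse_query("~1Ibuhexal"), ix$index)$snippet,
    "Ibohexal 400mg"
  )
  expect_identical(
    execute(parse_query("delix -negated"), ix$index)$snippet,
    "Delix 5mg 1-0-0"
  )
})
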