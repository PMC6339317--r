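# Shared fixture builders: everything is constructed in code at test time.

# sentence table + annotated tokens + index from bare instruction strings
make_index <- function(texts, triggers = default_trigger_lexicon(),
                       label = "medication") {
  sents <- tibble::tibble(
    doc_id = paste0("d", seq_along(texts)),
    sentence_id = paste0("s", seq_along(texts)),
    section_id = "sec1", label = label, historical = FALSE,
    text = texts, start = 0L, end = nchar(texts)
  )
  toks <- annotate_context(tokenize_sentences(sents), triggers,
                           sentences = sents)
  list(sentences = sents, tokens = toks,
       index = build_index(sents, toks))
}

# sentence list in the shape the scan oracle expects
oracle_sents_from_index <- function(ix) {
  sent <- ix$index$sentences
  out <- lapply(seq_len(nrow(sent)), function(i) {
    st <- ix$index$sent_tokens[[sent$sentence_id[i]]]
    list(
      norms = st$norm,
      flags = list(
        negated = sent$negated[i], historical = sent$historical[i],
        other_subject = sent$other_subject[i],
        discontinued = sent$discontinued[i]
      )
    )
  })
  names(out) <- sent$sentence_id
  out
}

# random instruction-like sentences over a small vocabulary
random_corpus_texts <- function(n_sentences, rng_vocab = NULL) {
  vocab <- rng_vocab %||% c("delix", "esidrix", "concor", "mg", "aber",
                            "1", "0", "1/2", "5", "10", "kein", "zok")
  vapply(seq_len(n_sentences), function(i) {
    k <- sample(2:8, 1)
    paste(sample(vocab, k, replace = TRUE), collapse = " ")
  }, character(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# printed per-drug dose distributions (daily units x strength -> share),
# assembled from the published percentage tables
eliquis_distribution <- function() {
  tibble::tibble(
    daily_units = c(1, 1, 2, 2, 3),
    strength = c(2.5, 5, 2.5, 5, 5),
    proportion = c(0.037, 0.032, 0.432, 0.495, 0.005)
  )
}

pradaxa_distribution <- function() {
  tibble::tibble(
    daily_units = c(1, 1, 1, 2, 2, 2, 2, 3),
    strength = c(75, 110, 150, 10, 75, 110, 150, 110),
    proportion = c(0.011, 0.056, 0.033, 0.011, 0.039, 0.511, 0.333,
                   0.006)
  )
}

xarelto_distribution <- function() {
  tibble::tibble(
    daily_units = c(1, 1, 1, 1, 2, 2, 2, 3),
    strength = c(10, 15, 20, 50, 10, 15, 20, 20),
    proportion = c(0.009, 0.266, 0.674, 0.005, 0.014, 0.014, 0.014,
                   0.005)
  )
}

# the two-plus-one disjunct expansion printed for the worked dose query
table3_catalog <- function() {
  list("1" = list(c(1, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5)))
}
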