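#' Build a positional in-memory index over instruction sentences
#'
#' The index is the stand-in for a search-server backend: a postings table
#' mapping each normalized token to its (document, sentence, position)
#' occurrences, plus a sentence store carrying text and context flags.
#' Queries built with the [query] constructors run against it via
#' [execute()].
#'
#' @param sentences Sentence tibble ([segment_instructions()] /
#'   [segment_lines()]).
#' @param tokens Token tibble, ideally context-annotated
#'   ([annotate_context()]); missing flag columns are treated as all-false.
#' @return An object of class `medex_index`.
#' @export
build_index <- function(sentences, tokens) {
  stopifnot(is.data.frame(sentences), is.data.frame(tokens))
  if (anyDuplicated(sentences$sentence_id)) {
    abort("duplicate sentence_id in sentence store")
  }
  flags <- sentence_context_flags(ensure_flag_cols(tokens))
  sent <- left_join(sentences, flags, by = "sentence_id",
                    suffix = c(".sec", ""))
  for (f in c("negated", "historical", "other_subject", "discontinued")) {
    if (!f %in% names(sent)) sent[[f]] <- FALSE
    sent[[f]][is.na(sent[[f]])] <- FALSE
  }
  if ("historical.sec" %in% names(sent)) {
    sent$historical <- sent$historical | sent$historical.sec
    sent$historical.sec <- NULL
  }
  tokens <- tokens[order(match(tokens$sentence_id, sent$sentence_id),
                         tokens$idx), , drop = FALSE]
  bad <- !tokens$sentence_id %in% sent$sentence_id
  if (any(bad)) abort("token rows reference unknown sentence_id")
  sent_tokens <- lapply(
    split(tokens[, c("idx", "norm", "kind", "value")],
          factor(tokens$sentence_id, levels = sent$sentence_id)),
    as.list
  )
  structure(
    list(
      sentences = sent,
      postings = tokens,
      sent_tokens = sent_tokens,
      vocab = sort(unique(tokens$norm))
    ),
    class = "medex_index"
  )
}

ensure_flag_cols <- function(tokens) {
  for (f in c("negated", "historical", "other_subject", "discontinued",
              "is_trigger")) {
    if (!f %in% names(tokens)) tokens[[f]] <- FALSE
  }
  tokens
}

#' @export
print.medex_index <- function(x, ...) {
  cat(sprintf(
    "<medex_index> %d sentences over %d documents, %d postings, vocabulary %d\n",
    nrow(x$sentences), dplyr::n_distinct(x$sentences$doc_id),
    nrow(x$postings), length(x$vocab)
  ))
  invisible(x)
}

# vocabulary tokens equal to a query token: exact norm match, or equal
# numeric value when both sides are numbers ("1/2" matches "0,5")
match_vocab <- function(token, index, fuzzy = FALSE, max_dist = NULL) {
  tl <- tolower(token)
  hits <- if (fuzzy) {
    fuzzy_expand(tl, index$vocab, max_dist = max_dist)
  } else {
    index$vocab[index$vocab == tl]
  }
  qv <- token_value(tl)
  if (!is.na(qv)) {
    vv <- token_value(index$vocab)
    hits <- union(hits, index$vocab[!is.na(vv) & abs(vv - qv) < 1e-9])
  }
  hits
}

token_value <- function(x) {
  out <- rep(NA_real_, length(x))
  frac <- grepl("^[0-9]+/[0-9]+$", x)
  if (any(frac)) {
    p <- strsplit(x[frac], "/", fixed = TRUE)
    num <- vapply(p, function(z) as.numeric(z[1]) / as.numeric(z[2]),
                  numeric(1))
    ok <- num < 1  # proper fractions only, mirroring the tokenizer
    out[frac][ok] <- num[ok]
  }
  dec <- grepl("^[0-9]+[.,][0-9]+$", x)
  out[dec] <- as.numeric(sub(",", ".", x[dec], fixed = TRUE))
  int <- grepl("^[0-9]+$", x)
  out[int] <- as.numeric(x[int])
  out
}

#' Execute a query against a positional index
#'
#' Evaluates the query tree and returns one hit per matching sentence.
#' Boolean nodes combine matches by sentence-set algebra (NOT is the
#' complement over all indexed sentences); the `active` node drops
#' sentences whose context flags match its exclusion list.
#'
#' @param query A `medex_query` (see [query] or [parse_query()]).
#' @param index A `medex_index` from [build_index()].
#' @return A tibble of hits: `doc_id`, `sentence_id`, `matched` (list of
#'   0-based token indices witnessing the match) and `snippet` (the
#'   sentence text).
#' @export
execute <- function(query, index) {
  stopifnot(inherits(query, "medex_query"), inherits(index, "medex_index"))
  res <- eval_node(query, index)
  sent <- index$sentences
  ord <- match(res$sentence_id, sent$sentence_id)
  tibble(
    doc_id = sent$doc_id[ord],
    sentence_id = res$sentence_id,
    matched = res$matched,
    snippet = sent$text[ord]
  ) %>% arrange(match(sentence_id, sent$sentence_id))
}

empty_result <- function() {
  tibble(sentence_id = character(), matched = list())
}

result_from_postings <- function(post) {
  if (nrow(post) == 0L) return(empty_result())
  post %>%
    group_by(sentence_id) %>%
    summarise(matched = list(sort(unique(idx))), .groups = "drop")
}

eval_node <- function(q, index) {
  switch(q$kind,
    term = eval_tokenset(match_vocab(q$token, index), index),
    fuzzy = eval_tokenset(
      match_vocab(q$token, index, fuzzy = TRUE, max_dist = q$max_dist),
      index),
    regex = eval_tokenset(
      grep(q$pattern, index$vocab, value = TRUE, perl = TRUE,
           ignore.case = TRUE),
      index),
    phrase = eval_phrase(q, index),
    near = eval_near(q, index),
    and = eval_and(q, index),
    or = eval_or(q, index),
    not = eval_not(q, index),
    active = eval_active(q, index),
    abort(sprintf("unknown query node kind '%s'", q$kind))
  )
}

eval_tokenset <- function(vocab_hits, index) {
  if (length(vocab_hits) == 0L) return(empty_result())
  result_from_postings(
    index$postings[index$postings$norm %in% vocab_hits, , drop = FALSE]
  )
}

eval_and <- function(q, index) {
  parts <- lapply(q$children, eval_node, index = index)
  ids <- Reduce(intersect, lapply(parts, function(p) p$sentence_id))
  if (length(ids) == 0L) return(empty_result())
  matched <- lapply(ids, function(id) {
    sort(unique(unlist(lapply(parts, function(p) {
      p$matched[p$sentence_id == id]
    }))))
  })
  tibble(sentence_id = ids, matched = matched)
}

eval_or <- function(q, index) {
  parts <- bind_rows(lapply(q$children, eval_node, index = index))
  if (nrow(parts) == 0L) return(empty_result())
  parts %>%
    group_by(sentence_id) %>%
    summarise(matched = list(sort(unique(unlist(matched)))),
              .groups = "drop")
}

eval_not <- function(q, index) {
  inner <- eval_node(q$child, index)
  ids <- setdiff(index$sentences$sentence_id, inner$sentence_id)
  tibble(sentence_id = ids,
         matched = rep(list(integer(0)), length(ids)))
}

eval_active <- function(q, index) {
  base <- if (is.null(q$child)) {
    ids <- index$sentences$sentence_id
    tibble(sentence_id = ids,
           matched = rep(list(integer(0)), length(ids)))
  } else {
    eval_node(q$child, index)
  }
  sent <- index$sentences
  bad <- rep(FALSE, nrow(sent))
  for (f in q$exclude) bad <- bad | sent[[f]]
  base[!base$sentence_id %in% sent$sentence_id[bad], , drop = FALSE]
}

eval_phrase <- function(q, index) {
  vocab_per_tok <- lapply(q$tokens, match_vocab, index = index)
  if (any(lengths(vocab_per_tok) == 0L)) return(empty_result())
  cand <- Reduce(intersect, lapply(vocab_per_tok, function(v) {
    unique(index$postings$sentence_id[index$postings$norm %in% v])
  }))
  rows <- purrr::map(cand, function(sid) {
    st <- index$sent_tokens[[sid]]
    k <- length(q$tokens)
    n <- length(st$norm)
    if (n < k) return(NULL)
    for (s in 1:(n - k + 1L)) {
      if (all(vapply(seq_len(k), function(j) {
        st$norm[s + j - 1L] %in% vocab_per_tok[[j]]
      }, logical(1)))) {
        return(tibble(sentence_id = sid,
                      matched = list(st$idx[s:(s + k - 1L)])))
      }
    }
    NULL
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) empty_result() else out
}

eval_near <- function(q, index) {
  vocab_per_tok <- lapply(q$tokens, match_vocab, index = index)
  if (any(lengths(vocab_per_tok) == 0L)) return(empty_result())
  cand <- Reduce(intersect, lapply(vocab_per_tok, function(v) {
    unique(index$postings$sentence_id[index$postings$norm %in% v])
  }))
  k <- length(q$tokens)
  window <- k + q$slop
  numeric_mask <- !is.na(token_value(tolower(q$tokens)))
  rows <- purrr::map(cand, function(sid) {
    st <- index$sent_tokens[[sid]]
    opts <- lapply(vocab_per_tok, function(v) st$idx[st$norm %in% v])
    if (any(lengths(opts) == 0L)) return(NULL)
    hit <- near_assign(opts, window, numeric_mask,
                       ordered = q$ordered_numbers)
    if (is.null(hit)) return(NULL)
    tibble(sentence_id = sid, matched = list(sort(hit)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) empty_result() else out
}

# backtracking assignment of query tokens to distinct sentence positions
# under the window bound and (optionally) increasing positions for numeric
# query tokens in their given order
near_assign <- function(opts, window, numeric_mask, ordered) {
  k <- length(opts)
  assign_rec <- function(j, chosen, last_num) {
    if (j > k) {
      if (max(chosen) - min(chosen) + 1L <= window) return(chosen)
      return(NULL)
    }
    for (p in opts[[j]]) {
      if (p %in% chosen) next
      if (ordered && numeric_mask[j] && !is.null(last_num) &&
          p <= last_num) next
      if (length(chosen) &&
          max(c(chosen, p)) - min(c(chosen, p)) + 1L > window) next
      res <- assign_rec(j + 1L, c(chosen, p),
                        if (numeric_mask[j]) p else last_num)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  assign_rec(1L, integer(0), NULL)
}
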