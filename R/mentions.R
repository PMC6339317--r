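#' Find drug-name mentions in indexed sentences
#'
#' Scans the index for occurrences of every lexicon query term (processed
#' product names and alternative names), exactly or error-tolerantly:
#' with `fuzzy = TRUE` each name token may differ from the text token by
#' up to the length-dependent Damerau-Levenshtein threshold of
#' [fuzzy_max_dist()].  Overlapping matches inside a sentence are resolved
#' in favour of the longest term.
#'
#' @param index A `medex_index`.
#' @param db Drug lexicon from [read_drug_db()].
#' @param fuzzy Enable error-tolerant matching.
#' @return A tibble with one row per mention: `doc_id`, `sentence_id`,
#'   `canonical` (lexicon product name), `atc_code`, `term` (matched query
#'   term), `token_start`, `token_end` (0-based token indices), `start`,
#'   `end` (0-based half-open character offsets within the sentence) and
#'   the sentence's four context flags.
#' @export
find_drug_mentions <- function(index, db, fuzzy = TRUE) {
  stopifnot(inherits(index, "medex_index"))
  terms <- db_terms(db)
  if (nrow(terms) == 0L || nrow(index$postings) == 0L) {
    return(empty_mentions())
  }
  # map each distinct first token to its vocabulary matches once
  firsts <- unique(terms$first_tok)
  first_map <- lapply(firsts, function(ft) {
    match_vocab(ft, index, fuzzy = fuzzy)
  })
  names(first_map) <- firsts
  post <- index$postings
  acc_term <- integer(0)   # row index into terms
  acc_row <- integer(0)    # row index into post
  for (t in seq_len(nrow(terms))) {
    toks <- terms$tokens[[t]]
    vhits <- first_map[[terms$first_tok[t]]]
    if (length(vhits) == 0L) next
    cand <- which(post$norm %in% vhits)
    if (length(cand) == 0L) next
    if (length(toks) > 1L) {
      ok <- vapply(cand, function(r) {
        sid <- post$sentence_id[r]
        st <- index$sent_tokens[[sid]]
        pos0 <- match(post$idx[r], st$idx)
        for (j in 2:length(toks)) {
          p <- pos0 + j - 1L
          if (p > length(st$norm) ||
              st$idx[p] != post$idx[r] + j - 1L ||
              !token_eq(toks[j], st$norm[p], fuzzy)) {
            return(FALSE)
          }
        }
        TRUE
      }, logical(1))
      cand <- cand[ok]
    }
    acc_term <- c(acc_term, rep.int(t, length(cand)))
    acc_row <- c(acc_row, cand)
  }
  if (length(acc_row) == 0L) return(empty_mentions())
  n_tok_per_term <- lengths(terms$tokens)
  out <- tibble(
    doc_id = post$doc_id[acc_row],
    sentence_id = post$sentence_id[acc_row],
    canonical = terms$canonical[acc_term],
    atc_code = terms$atc_code[acc_term],
    term = terms$term[acc_term],
    token_start = post$idx[acc_row],
    token_end = post$idx[acc_row] + n_tok_per_term[acc_term] - 1L,
    n_tok = n_tok_per_term[acc_term]
  )
  out <- resolve_overlaps(out)
  attach_mention_spans(out, index)
}

empty_mentions <- function() {
  tibble(
    doc_id = character(0), sentence_id = character(0),
    canonical = character(0), atc_code = character(0),
    term = character(0), token_start = integer(0), token_end = integer(0),
    start = integer(0), end = integer(0),
    negated = logical(0), historical = logical(0),
    other_subject = logical(0), discontinued = logical(0)
  )
}

db_terms <- function(db) {
  rows <- purrr::map(seq_len(nrow(db)), function(i) {
    seqs <- c(list(db$processed[[i]]), db$alt[[i]])
    seqs <- seqs[lengths(seqs) > 0L]
    if (length(seqs) == 0L) return(NULL)
    tibble(
      canonical = db$product_name[i],
      atc_code = db$atc_code[i],
      term = vapply(seqs, paste, character(1), collapse = " "),
      tokens = purrr::map(seqs, tolower),
      first_tok = vapply(seqs, function(s) tolower(s[1]), character(1))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out[!duplicated(tolower(out$term)), , drop = FALSE]
}

token_eq <- function(query_tok, text_norm, fuzzy) {
  if (tolower(query_tok) == text_norm) return(TRUE)
  if (!fuzzy) return(FALSE)
  d <- fuzzy_max_dist(query_tok)
  d > 0L && dl_distance(tolower(query_tok), text_norm) <= d
}

# longest-match-wins within a sentence; equal-length duplicates on the
# same span collapse to the first
resolve_overlaps <- function(mentions) {
  mentions %>%
    group_by(sentence_id) %>%
    arrange(dplyr::desc(n_tok), token_start, .by_group = TRUE) %>%
    filter(!purrr::map_lgl(row_number(), function(i) {
      any(token_start[i] <= token_end[seq_len(i - 1L)] &
            token_end[i] >= token_start[seq_len(i - 1L)])
    })) %>%
    ungroup() %>%
    arrange(sentence_id, token_start) %>%
    select(-n_tok)
}

attach_mention_spans <- function(mentions, index) {
  post <- index$postings
  key <- paste(post$sentence_id, post$idx)
  s_at <- setNames(post$start, key)
  e_at <- setNames(post$end, key)
  mentions$start <- unname(s_at[paste(mentions$sentence_id,
                                      mentions$token_start)])
  mentions$end <- unname(e_at[paste(mentions$sentence_id,
                                    mentions$token_end)])
  sent <- index$sentences
  ord <- match(mentions$sentence_id, sent$sentence_id)
  for (f in c("negated", "historical", "other_subject", "discontinued")) {
    mentions[[f]] <- sent[[f]][ord]
  }
  mentions
}

#' Extract current medications with parsed daily doses
#'
#' The end-to-end extraction: finds drug mentions, drops those whose
#' context disqualifies them (negated, historical, other-subject,
#' discontinued), and parses strength, dosing pattern and daily dose from
#' the tokens following each mention.
#'
#' @param index A `medex_index` built over context-annotated tokens.
#' @param db Drug lexicon.
#' @param fuzzy Enable error-tolerant name matching.
#' @param exclude Context flags that disqualify a mention; use
#'   `character(0)` to keep everything.
#' @param max_gap,pattern_gap Dose-parsing windows, see
#'   [parse_dose_instruction()].
#' @return A tibble: mention columns from [find_drug_mentions()] plus
#'   `strength`, `unit`, `pattern`, `daily_units`, `daily_dose`.
#' @export
extract_medications <- function(index, db, fuzzy = TRUE,
                                exclude = c("negated", "historical",
                                            "other_subject",
                                            "discontinued"),
                                max_gap = 2L, pattern_gap = 4L) {
  mentions <- find_drug_mentions(index, db, fuzzy = fuzzy)
  if (length(exclude)) {
    bad <- rep(FALSE, nrow(mentions))
    for (f in exclude) bad <- bad | mentions[[f]]
    mentions <- mentions[!bad, , drop = FALSE]
  }
  if (nrow(mentions) == 0L) {
    out <- mentions
    out$strength <- numeric(0)
    out$unit <- character(0)
    out$pattern <- list()
    out$daily_units <- numeric(0)
    out$daily_dose <- numeric(0)
    return(out)
  }
  n <- nrow(mentions)
  strength <- daily_units <- daily_dose <- rep(NA_real_, n)
  unit <- rep(NA_character_, n)
  pattern <- vector("list", n)
  for (i in seq_len(n)) {
    st <- index$sent_tokens[[mentions$sentence_id[i]]]
    r <- parse_dose_core(st$idx, st$kind, st$value, st$norm,
                         mentions$token_end[i],
                         max_gap = max_gap, pattern_gap = pattern_gap)
    strength[i] <- r$strength
    unit[i] <- r$unit
    pattern[i] <- list(r$pattern)  # keeps NULL as an element
    daily_units[i] <- r$daily_units
    daily_dose[i] <- r$daily_dose
  }
  mentions$strength <- strength
  mentions$unit <- unit
  mentions$pattern <- pattern
  mentions$daily_units <- daily_units
  mentions$daily_dose <- daily_dose
  mentions
}

#' @importFrom dplyr bind_cols
NULL
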