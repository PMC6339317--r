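#' Default ConText trigger lexicon
#'
#' Bilingual trigger phrases for the four context categories used when
#' filtering medication mentions: `negation` ("kein", "no", ...),
#' `discontinuation` ("abgesetzt", "pausiert", "stopped", ...),
#' `historical` ("bei Aufnahme", "Vormedikation", ...), and
#' `other_subject` ("Mutter", "family history", ...).  Forward triggers
#' scope to the end of the sentence, backward triggers to its start;
#' scope is cut at the terminator tokens ("aber", "but").  The list is a
#' configurable stand-in: extend it with [read_trigger_lexicon()] to match
#' local documentation style.
#'
#' @return A tibble with columns `phrase`, `category`, `direction`
#'   (`forward`, `backward`, `bidirectional`) and `terminators`
#'   (comma-separated phrase list).
#' @export
default_trigger_lexicon <- function() {
  read_trigger_lexicon(
    system.file("extdata", "context_triggers.tsv", package = "medtrawl")
  )
}

#' Read a ConText trigger lexicon from TSV
#'
#' @param path Tab-separated file with columns `phrase`, `category`,
#'   `direction`, `terminators` (comma-separated, may be empty).
#' @return Trigger tibble as in [default_trigger_lexicon()].
#' @export
read_trigger_lexicon <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "#",
                          fileEncoding = "UTF-8")
  stopifnot(all(c("phrase", "category", "direction") %in% names(df)))
  if (is.null(df$terminators)) df$terminators <- ""
  bad <- !df$category %in% c("negation", "historical", "other_subject",
                             "discontinuation")
  if (any(bad)) {
    abort(sprintf("invalid trigger category in rows: %s",
                  paste(which(bad), collapse = ", ")))
  }
  bad <- !df$direction %in% c("forward", "backward", "bidirectional")
  if (any(bad)) {
    abort(sprintf("invalid trigger direction in rows: %s",
                  paste(which(bad), collapse = ", ")))
  }
  tibble(phrase = df$phrase, category = df$category,
         direction = df$direction,
         terminators = ifelse(is.na(df$terminators), "", df$terminators))
}

trigger_category_flag <- function(category) {
  c(negation = "negated", historical = "historical",
    other_subject = "other_subject",
    discontinuation = "discontinued")[category]
}

#' Annotate tokens with ConText flags
#'
#' NegEx/ConText-style scope marking: each trigger phrase found in a
#' sentence sets its category flag (`negated`, `historical`,
#' `other_subject`, `discontinued`) on the tokens inside its scope — from
#' the trigger to the sentence end for forward triggers, back to the
#' sentence start for backward triggers — stopping at a scope terminator.
#' Tokens belonging to a trigger phrase itself are marked `is_trigger`.
#' Sentences from sections marked historical (admission-medication
#' headers) get `historical` on every token.
#'
#' @param tokens Token tibble from [tokenize_sentences()].
#' @param triggers Trigger lexicon tibble, see [default_trigger_lexicon()].
#' @param sentences Optional sentence tibble carrying a `historical`
#'   column for section-level historical marking.
#' @return `tokens` with added logical columns `negated`, `historical`,
#'   `other_subject`, `discontinued`, `is_trigger`.
#' @export
annotate_context <- function(tokens, triggers = default_trigger_lexicon(),
                             sentences = NULL) {
  flags <- c("negated", "historical", "other_subject", "discontinued")
  for (f in flags) tokens[[f]] <- FALSE
  tokens$is_trigger <- FALSE
  if (nrow(tokens) == 0L) return(tokens)

  trig <- compile_triggers(triggers)
  sent_ids <- unique(tokens$sentence_id)
  tokens <- tokens[order(match(tokens$sentence_id, sent_ids), tokens$idx), ]
  grp <- split(seq_len(nrow(tokens)), tokens$sentence_id)

  if (nrow(trig$tbl) > 0L) {
    trigger_toks <- unique(unlist(trig$phrases))
    for (rows in grp) {
      norms <- tokens$norm[rows]
      if (!any(norms %in% trigger_toks)) next
      res <- mark_sentence(norms, trig)
      for (f in flags) {
        tokens[[f]][rows] <- tokens[[f]][rows] | res$flags[, f]
      }
      tokens$is_trigger[rows] <- tokens$is_trigger[rows] | res$is_trigger
    }
  }
  if (!is.null(sentences) && "historical" %in% names(sentences)) {
    hist_ids <- sentences$sentence_id[sentences$historical]
    tokens$historical <- tokens$historical |
      tokens$sentence_id %in% hist_ids
  }
  tokens
}

compile_triggers <- function(triggers) {
  if (nrow(triggers) == 0L) {
    return(list(tbl = triggers, phrases = list(), terms = list()))
  }
  phrases <- purrr::map(triggers$phrase, function(p) tokenize(p)$norm)
  terms <- purrr::map(triggers$terminators, function(t) {
    if (is.na(t) || !nzchar(t)) return(character(0))
    unlist(purrr::map(strsplit(t, ",")[[1L]],
                      function(x) tokenize(trimws(x))$norm))
  })
  list(tbl = triggers, phrases = phrases, terms = terms)
}

find_phrase <- function(norms, phrase) {
  np <- length(phrase)
  nn <- length(norms)
  if (np == 0L || nn < np) return(integer(0))
  starts <- which(norms == phrase[1])
  starts <- starts[starts + np - 1L <= nn]
  keep <- vapply(starts, function(s) {
    all(norms[s:(s + np - 1L)] == phrase)
  }, logical(1))
  starts[keep]
}

mark_sentence <- function(norms, trig) {
  nn <- length(norms)
  flags <- matrix(FALSE, nrow = nn, ncol = 4,
                  dimnames = list(NULL, c("negated", "historical",
                                          "other_subject", "discontinued")))
  is_trigger <- rep(FALSE, nn)
  for (r in seq_len(nrow(trig$tbl))) {
    phrase <- trig$phrases[[r]]
    occ <- find_phrase(norms, phrase)
    if (length(occ) == 0L) next
    flag <- trigger_category_flag(trig$tbl$category[r])
    dir <- trig$tbl$direction[r]
    term_pos <- which(norms %in% trig$terms[[r]])
    for (s in occ) {
      e <- s + length(phrase) - 1L
      is_trigger[s:e] <- TRUE
      if (dir %in% c("forward", "bidirectional") && e < nn) {
        stop_at <- term_pos[term_pos > e]
        hi <- if (length(stop_at)) min(stop_at) - 1L else nn
        if (hi > e) flags[(e + 1L):hi, flag] <- TRUE
      }
      if (dir %in% c("backward", "bidirectional") && s > 1L) {
        stop_at <- term_pos[term_pos < s]
        lo <- if (length(stop_at)) max(stop_at) + 1L else 1L
        if (lo < s) flags[lo:(s - 1L), flag] <- TRUE
      }
    }
  }
  list(flags = flags, is_trigger = is_trigger)
}

#' Summarise context flags per sentence
#'
#' A sentence carries a flag when any of its non-trigger tokens carries it.
#'
#' @param tokens Annotated token tibble from [annotate_context()].
#' @return A tibble with `sentence_id` and the four logical flag columns.
#' @export
sentence_context_flags <- function(tokens) {
  if (nrow(tokens) == 0L) {
    return(tibble(sentence_id = character(), negated = logical(),
                  historical = logical(), other_subject = logical(),
                  discontinued = logical()))
  }
  tokens %>%
    group_by(sentence_id) %>%
    summarise(
      negated = any(negated & !is_trigger),
      historical = any(historical & !is_trigger),
      other_subject = any(other_subject & !is_trigger),
      discontinued = any(discontinued & !is_trigger),
      .groups = "drop"
    )
}

#' Filter instruction sentences to currently valid medication
#'
#' Drops sentences flagged negated, historical, other-subject, or
#' discontinued, keeping only medication the patient currently takes.
#' Order is preserved; with an empty trigger lexicon (all flags false) this
#' is the identity and it is idempotent.
#'
#' @param sentences Sentence tibble.
#' @param tokens Annotated token tibble from [annotate_context()].
#' @param drop Character vector of flags that disqualify a sentence.
#' @return The subset of `sentences` with no disqualifying flag, with the
#'   four flag columns attached.
#' @export
filter_active <- function(sentences, tokens,
                          drop = c("negated", "historical",
                                   "other_subject", "discontinued")) {
  flags <- sentence_context_flags(tokens)
  merged <- left_join(sentences, flags, by = "sentence_id",
                      suffix = c(".sec", ""))
  for (f in c("negated", "historical", "other_subject", "discontinued")) {
    if (!f %in% names(merged)) merged[[f]] <- FALSE
    merged[[f]][is.na(merged[[f]])] <- FALSE
  }
  if ("historical.sec" %in% names(merged)) {
    merged$historical <- merged$historical | merged$historical.sec
    merged$historical.sec <- NULL
  }
  bad <- rep(FALSE, nrow(merged))
  for (f in drop) bad <- bad | merged[[f]]
  merged[!bad, , drop = FALSE]
}
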