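#' Default section-header lexicon
#'
#' Bilingual (German/English) line-start header patterns that open labeled
#' sections of a discharge letter.  A header line matches when the line
#' starts with the pattern (case-insensitively) followed by an optional
#' colon.  Admission-medication headers are marked `historical`: their whole
#' section describes medication at admission, not current medication.
#'
#' @return A tibble with columns `pattern`, `label` (one of `diagnoses`,
#'   `medication`, `laboratory`, `other`) and `historical` (logical).
#' @export
default_section_headers <- function() {
  read_section_headers(
    system.file("extdata", "section_headers.tsv", package = "medtrawl")
  )
}

#' Read a section-header lexicon from TSV
#'
#' @param path Path to a tab-separated file with columns
#'   `pattern`, `label`, `historical` (0/1).
#' @return A tibble as in [default_section_headers()].
#' @export
read_section_headers <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "#",
                          fileEncoding = "UTF-8")
  stopifnot(all(c("pattern", "label") %in% names(df)))
  if (is.null(df$historical)) df$historical <- 0L
  ok <- df$label %in% c("diagnoses", "medication", "laboratory", "other")
  if (!all(ok)) {
    abort(sprintf("invalid section label(s): %s",
                  paste(unique(df$label[!ok]), collapse = ", ")))
  }
  tibble(pattern = df$pattern, label = df$label,
         historical = as.logical(df$historical))
}

#' Split documents into labeled sections
#'
#' Scans each document line by line for recognised section headers and cuts
#' the text into contiguous, non-overlapping sections that together cover
#' the whole document.  Text before the first recognised header is labeled
#' `other`.  A section's `text` excludes its header line; its character span
#' `[start, end)` (0-based, half-open) includes it, so spans tile the
#' document.
#'
#' @param docs A tibble of documents with at least `doc_id` and `text`
#'   columns (see [read_corpus_jsonl()]).
#' @param headers Header lexicon tibble, see [default_section_headers()].
#' @return A tibble with one row per section: `doc_id`, `section_id`,
#'   `label`, `historical`, `header`, `start`, `end`, `body_start`, `text`.
#' @export
split_sections <- function(docs, headers = default_section_headers()) {
  stopifnot(is.data.frame(docs), all(c("doc_id", "text") %in% names(docs)),
            nrow(headers) > 0L)
  # longest pattern first so "Medikation bei Aufnahme" beats "Medikation"
  headers <- headers[order(-nchar(headers$pattern)), ]
  out <- purrr::map(seq_len(nrow(docs)), function(i) {
    split_sections_one(docs$text[i], headers)
  })
  n_per <- vapply(out, function(o) length(o$start), integer(1))
  src <- rep(seq_len(nrow(docs)), n_per)
  sec_num <- sequence(n_per)
  tibble(
    doc_id = docs$doc_id[src],
    section_id = paste0(docs$doc_id[src], "/s", sec_num),
    label = unlist(lapply(out, `[[`, "label"), use.names = FALSE),
    historical = unlist(lapply(out, `[[`, "historical"),
                        use.names = FALSE),
    header = unlist(lapply(out, `[[`, "header"), use.names = FALSE),
    start = unlist(lapply(out, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(out, `[[`, "end"), use.names = FALSE),
    body_start = unlist(lapply(out, `[[`, "body_start"),
                        use.names = FALSE),
    text = unlist(lapply(out, `[[`, "text"), use.names = FALSE)
  )
}

split_sections_one <- function(text, headers) {
  if (is.na(text)) text <- ""
  if (!nzchar(text)) {
    return(list(label = "other", historical = FALSE,
                header = NA_character_, start = 0L, end = 0L,
                body_start = 0L, text = ""))
  }
  # line starts (0-based)
  nl <- gregexpr("\n", text, fixed = TRUE)[[1L]]
  nl <- if (nl[1] == -1L) integer(0) else as.integer(nl)
  line_start <- c(0L, nl)                      # 0-based
  line_end <- c(nl - 1L, nchar(text))          # exclusive, 0-based
  lines <- substring(text, line_start + 1L, line_end)

  hdr <- match_header(lines, headers)
  cut_idx <- which(!is.na(hdr$label))

  if (length(cut_idx) == 0L) {
    return(list(label = "other", historical = FALSE,
                header = NA_character_, start = 0L,
                end = nchar(text), body_start = 0L, text = text))
  }
  label <- character(0)
  historical <- logical(0)
  header <- character(0)
  start <- end <- body_start <- integer(0)
  first_cut <- line_start[cut_idx[1]]
  if (first_cut > 0L) {
    label <- "other"
    historical <- FALSE
    header <- NA_character_
    start <- 0L
    end <- first_cut
    body_start <- 0L
  }
  for (j in seq_along(cut_idx)) {
    li <- cut_idx[j]
    sec_end <- if (j < length(cut_idx)) line_start[cut_idx[j + 1]]
               else nchar(text)
    label <- c(label, hdr$label[li])
    historical <- c(historical, hdr$historical[li])
    header <- c(header, trimws(lines[li]))
    start <- c(start, line_start[li])
    end <- c(end, sec_end)
    body_start <- c(body_start,
                    min(line_end[li] + 1L, sec_end))  # skip header line
  }
  list(label = label, historical = historical, header = header,
       start = start, end = end, body_start = body_start,
       text = substring(text, body_start + 1L, end))
}

match_header <- function(lines, headers) {
  lab <- rep(NA_character_, length(lines))
  hist <- rep(FALSE, length(lines))
  lt <- tolower(trimws(lines))
  for (h in seq_len(nrow(headers))) {
    p <- tolower(headers$pattern[h])
    cand <- is.na(lab) & startsWith(lt, p)
    if (!any(cand)) next
    rest <- substring(lt[cand], nchar(p) + 1L)
    ok <- rest == "" | grepl("^\\s*:", rest)
    ix <- which(cand)[ok]
    lab[ix] <- headers$label[h]
    hist[ix] <- headers$historical[h]
  }
  list(label = lab, historical = hist)
}

#' Segment a medication section into instruction sentences
#'
#' Splits medication-section text on instruction separators — newlines,
#' semicolons, and commas — into one sentence per drug instruction.  A comma
#' flanked by digits on both sides (a decimal comma as in `"12,5"`) is never
#' a separator.  Character offsets of each sentence refer to the original
#' document text, so the section text can be reconstructed from the spans.
#'
#' @param sections Sections tibble from [split_sections()]; only rows with
#'   `label == "medication"` are segmented.
#' @return A tibble with one row per instruction sentence: `doc_id`,
#'   `sentence_id`, `section_id`, `label`, `historical`, `text`, and
#'   0-based half-open `start`, `end` offsets into the document text.
#' @export
segment_instructions <- function(sections) {
  med <- sections[sections$label == "medication", , drop = FALSE]
  out <- purrr::map(seq_len(nrow(med)), function(i) {
    segment_one(med$text[i], med$body_start[i], med$section_id[i])
  })
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) {
    return(empty_sentence_tbl())
  }
  out <- out[keep]
  med <- med[keep, , drop = FALSE]
  n_per <- vapply(out, function(o) length(o$start), integer(1))
  src <- rep(seq_along(out), n_per)
  tibble(
    doc_id = med$doc_id[src],
    sentence_id = unlist(lapply(out, `[[`, "sentence_id"),
                         use.names = FALSE),
    section_id = med$section_id[src],
    label = med$label[src],
    historical = med$historical[src],
    text = unlist(lapply(out, `[[`, "text"), use.names = FALSE),
    start = unlist(lapply(out, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(out, `[[`, "end"), use.names = FALSE)
  )
}

empty_sentence_tbl <- function() {
  tibble(
    doc_id = character(), sentence_id = character(),
    section_id = character(), label = character(), historical = logical(),
    text = character(), start = integer(), end = integer()
  )
}

segment_one <- function(txt, body_start, section_id) {
  if (!nzchar(txt)) return(NULL)
  # separator: newline, semicolon, or a comma not between two digits
  sep <- gregexpr("\n|;|,(?![0-9])|(?<![0-9]),", txt, perl = TRUE)[[1L]]
  sep <- if (sep[1] == -1L) integer(0) else as.integer(sep)
  piece_start <- c(1L, sep + 1L)
  piece_end <- c(sep - 1L, nchar(txt))
  raw <- substring(txt, piece_start, piece_end)
  lead <- nchar(raw) - nchar(sub("^\\s+", "", raw))
  trail <- nchar(raw) - nchar(sub("\\s+$", "", raw))
  s0 <- piece_start + lead
  e0 <- piece_end - trail
  keep <- e0 >= s0
  if (!any(keep)) return(NULL)
  s0 <- s0[keep]
  e0 <- e0[keep]
  list(
    sentence_id = paste0(section_id, "/i", seq_along(s0)),
    text = substring(txt, s0, e0),
    start = body_start + s0 - 1L,
    end = body_start + e0
  )
}

#' Segment non-medication sections line-wise
#'
#' Sections other than medication (diagnoses, laboratory, other) are split
#' into one sentence per non-empty line; no instruction-level segmentation
#' is attempted there.
#'
#' @param sections Sections tibble from [split_sections()].
#' @return A sentence tibble with the same columns as
#'   [segment_instructions()].
#' @export
segment_lines <- function(sections) {
  oth <- sections[sections$label != "medication", , drop = FALSE]
  out <- purrr::map(seq_len(nrow(oth)), function(i) {
    sec <- oth[i, ]
    txt <- sec$text
    if (!nzchar(txt)) return(NULL)
    nl <- gregexpr("\n", txt, fixed = TRUE)[[1L]]
    nl <- if (nl[1] == -1L) integer(0) else as.integer(nl)
    ps <- c(1L, nl + 1L)
    pe <- c(nl - 1L, nchar(txt))
    rows <- list()
    k <- 0L
    for (j in seq_along(ps)) {
      raw <- substring(txt, ps[j], pe[j])
      if (!nzchar(trimws(raw))) next
      lead <- nchar(raw) - nchar(sub("^\\s+", "", raw))
      trail <- nchar(raw) - nchar(sub("\\s+$", "", raw))
      k <- k + 1L
      rows[[k]] <- tibble(
        doc_id = sec$doc_id, sentence_id = paste0(sec$section_id, "/l", k),
        section_id = sec$section_id, label = sec$label,
        historical = sec$historical,
        text = substring(txt, ps[j] + lead, pe[j] - trail),
        start = sec$body_start + ps[j] + lead - 1L,
        end = sec$body_start + pe[j] - trail
      )
    }
    bind_rows(rows)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) empty_sentence_tbl() else res
}

#' Tokenize a sentence table
#'
#' Runs [tokenize()] over the `text` column and returns a long token table
#' keyed by `sentence_id`.
#'
#' @param sentences Sentence tibble from [segment_instructions()] or
#'   [segment_lines()].
#' @return A tibble of tokens with `doc_id`, `sentence_id`, `idx`,
#'   `surface`, `norm`, `kind`, `value`, `start`, `end` (offsets are within
#'   the sentence text).
#' @export
tokenize_sentences <- function(sentences) {
  if (nrow(sentences) == 0L) {
    tok <- empty_token_tbl()
    tok$doc_id <- character(0)
    tok$sentence_id <- character(0)
    tok$text_id <- NULL
    return(tok[, c("doc_id", "sentence_id", "idx", "surface", "norm",
                   "kind", "value", "start", "end")])
  }
  tok <- tokenize(sentences$text)
  tok$doc_id <- sentences$doc_id[tok$text_id]
  tok$sentence_id <- sentences$sentence_id[tok$text_id]
  tok[, c("doc_id", "sentence_id", "idx", "surface", "norm", "kind",
          "value", "start", "end")]
}
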