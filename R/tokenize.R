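#' Tokenize a medication instruction sentence
#'
#' Decomposes an instruction string into word and number tokens following the
#' conventions of medication sections in discharge letters: alphabetic and
#' numeric runs are split apart (`"10mg"` becomes `"10"`, `"mg"`), hyphens
#' and dashes act as token separators (`"1-0-0"` becomes three tokens,
#' `"Mono-Mack"` two), slash fractions such as `"1/2"` are kept as single
#' tokens, and decimal numbers written with a comma or point (`"12,5"`) are
#' kept whole.  No stemming is applied: drug-name endings are significant.
#'
#' A slash number is treated as a single `fraction` token only when its
#' numerator is smaller than its denominator (the dosing case); ratios like
#' the blood-pressure notation `"135/80"` are split into two integer tokens.
#'
#' @param sentence_text A character vector of sentences to tokenize.
#' @return A tibble with one row per token: `text_id` (position of the input
#'   sentence), `idx` (0-based token position), `surface` (original
#'   substring), `norm` (case-folded surface; umlauts and sharp-s are
#'   preserved), `kind` (one of `word`, `integer`, `decimal`, `fraction`,
#'   `unit`, `other`), `value` (parsed numeric value, `NA` for words), and
#'   0-based half-open character offsets `start`, `end` into the sentence.
#' @examples
#' tokenize("Delix 10mg 1-0-0")
#' tokenize("Belok zok 1/2-0-0")
#' @export
tokenize <- function(sentence_text) {
  stopifnot(is.character(sentence_text))
  if (length(sentence_text) == 0L) {
    return(empty_token_tbl())
  }
  pat <- "[0-9]+/[0-9]+|[0-9]+[.,][0-9]+|[0-9]+|\\p{L}+"
  ms <- gregexpr(pat, sentence_text, perl = TRUE)
  n_match <- vapply(ms, function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  starts <- unlist(lapply(ms, function(m) {
    if (m[1] == -1L) integer(0) else as.integer(m)
  }), use.names = FALSE)
  if (length(starts) == 0L) {
    return(empty_token_tbl())
  }
  mlens <- unlist(lapply(ms, function(m) {
    if (m[1] == -1L) integer(0) else attr(m, "match.length")
  }), use.names = FALSE)
  text_id <- rep(seq_along(sentence_text), n_match)
  ends <- starts + mlens - 1L
  surface <- substring(sentence_text[text_id], starts, ends)

  # improper slash ratios ("135/80") split into their two integer parts
  isfrac <- grepl("^[0-9]+/[0-9]+$", surface)
  numstr <- ifelse(isfrac, sub("/.*$", "", surface), NA)
  denstr <- ifelse(isfrac, sub("^.*/", "", surface), NA)
  improper <- isfrac & as.numeric(numstr) >= as.numeric(denstr)
  if (any(improper)) {
    rep_idx <- rep(seq_along(surface), 1L + improper)
    second <- duplicated(rep_idx)
    src <- rep_idx
    surface <- surface[src]
    starts <- starts[src]
    ends <- ends[src]
    text_id <- text_id[src]
    imp <- improper[src]
    nn <- nchar(numstr[src])
    surface[imp & !second] <- numstr[src][imp & !second]
    ends[imp & !second] <- starts[imp & !second] +
      nn[imp & !second] - 1L
    surface[imp & second] <- denstr[src][imp & second]
    starts[imp & second] <- starts[imp & second] +
      nn[imp & second] + 1L
  }

  idx <- sequence(tabulate(text_id, nbins = length(sentence_text))) - 1L
  norm <- tolower(surface)
  kind <- classify_token(norm)
  value <- rep(NA_real_, length(surface))
  fr <- kind == "fraction"
  value[fr] <- as.numeric(sub("/.*$", "", surface[fr])) /
    as.numeric(sub("^.*/", "", surface[fr]))
  de <- kind == "decimal"
  value[de] <- as.numeric(sub(",", ".", surface[de], fixed = TRUE))
  it <- kind == "integer"
  value[it] <- as.numeric(surface[it])
  tibble(
    text_id = text_id, idx = idx, surface = surface, norm = norm,
    kind = kind, value = value, start = starts - 1L, end = ends
  )
}

empty_token_tbl <- function() {
  tibble(
    text_id = integer(), idx = integer(), surface = character(),
    norm = character(), kind = character(), value = numeric(),
    start = integer(), end = integer()
  )
}

#' Dose units recognised by the tokenizer
#'
#' @return Character vector of unit tokens (case-folded).
#' @export
dose_units <- function() {
  c("mg", "µg", "ug", "g", "ml", "ie")
}

classify_token <- function(norm) {
  dplyr::case_when(
    grepl("^[0-9]+/[0-9]+$", norm) ~ "fraction",
    grepl("^[0-9]+[.,][0-9]+$", norm) ~ "decimal",
    grepl("^[0-9]+$", norm) ~ "integer",
    norm %in% dose_units() ~ "unit",
    grepl("^\\p{L}+$", norm, perl = TRUE) ~ "word",
    TRUE ~ "other"
  )
}

#' Parse a numeric token
#'
#' Converts the surface form of a numeric token to its value: slash
#' fractions (`"1/2"` is 0.5), decimal-comma or decimal-point numbers
#' (`"12,5"` is 12.5), and plain integers.
#'
#' @param x Character vector of numeric token surfaces.
#' @return Numeric vector of parsed non-negative values.
#' @examples
#' parse_number(c("1/2", "12,5", "0"))
#' @export
parse_number <- function(x) {
  stopifnot(is.character(x))
  vapply(seq_along(x), function(i) {
    s <- x[i]
    if (grepl("^[0-9]+/[0-9]+$", s)) {
      p <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1L]])
      return(p[1] / p[2])
    }
    if (grepl("^[0-9]+[.,][0-9]+$", s)) {
      return(as.numeric(sub(",", ".", s, fixed = TRUE)))
    }
    if (grepl("^[0-9]+$", s)) {
      return(as.numeric(s))
    }
    abort(sprintf("malformed numeric token '%s' at position %d", s, i))
  }, numeric(1))
}
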