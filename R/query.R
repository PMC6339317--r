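#' Query algebra over the positional index
#'
#' Constructors for the query tree evaluated by [execute()]: single-token
#' and error-tolerant token queries, contiguous phrases, proximity windows,
#' Boolean combinations, a vocabulary-level regular-expression matcher, and
#' a context-exclusion wrapper that drops negated/historical/other-subject/
#' discontinued sentences.
#'
#' Proximity (`query_near`) requires all its tokens, as a multiset, inside
#' a window of `length(tokens) + slop` token positions within a single
#' sentence; proximity never matches across sentence boundaries.  With
#' `ordered_numbers = TRUE` (the default) numeric tokens must occur in
#' their given relative order while word tokens are order-free — this keeps
#' a dose query like `Delix 5 1 0 0` from matching the instruction
#' `"Delix 5-mg 0 1 0"`, whose daily pattern is a different schedule.
#'
#' @param token,tokens Query token(s) (character).
#' @param max_dist Maximum edit distance for [query_fuzzy()]; `NULL` picks
#'   it from the token length via [fuzzy_max_dist()].
#' @param slop Extra window positions allowed beyond the token count
#'   (default 1, tolerating one interleaved token such as a unit).
#' @param ordered_numbers Keep numeric tokens order-preserving.
#' @param pattern Perl regular expression matched against the vocabulary.
#' @param query,... Child queries.
#' @param exclude Context flags that disqualify a sentence.
#' @return A query node of class `medex_query`.
#' @name query
NULL

q_node <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "medex_query")
}

#' @rdname query
#' @export
query_term <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  q_node("term", token = token)
}

#' @rdname query
#' @export
query_fuzzy <- function(token, max_dist = NULL) {
  stopifnot(is.character(token), length(token) == 1L)
  if (!is.null(max_dist)) stopifnot(max_dist >= 0L, max_dist <= 2L)
  q_node("fuzzy", token = token, max_dist = max_dist)
}

#' @rdname query
#' @export
query_phrase <- function(tokens) {
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  q_node("phrase", tokens = tokens)
}

#' @rdname query
#' @export
query_near <- function(tokens, slop = 1L, ordered_numbers = TRUE) {
  stopifnot(is.character(tokens), length(tokens) >= 2L, slop >= 0L)
  q_node("near", tokens = tokens, slop = as.integer(slop),
         ordered_numbers = isTRUE(ordered_numbers))
}

#' @rdname query
#' @export
query_regex <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  q_node("regex", pattern = pattern)
}

#' @rdname query
#' @export
query_and <- function(...) {
  ch <- list(...)
  stopifnot(length(ch) >= 1L, all(vapply(ch, inherits, logical(1),
                                         "medex_query")))
  q_node("and", children = ch)
}

#' @rdname query
#' @export
query_or <- function(...) {
  ch <- list(...)
  stopifnot(length(ch) >= 1L, all(vapply(ch, inherits, logical(1),
                                         "medex_query")))
  q_node("or", children = ch)
}

#' @rdname query
#' @export
query_not <- function(query) {
  stopifnot(inherits(query, "medex_query"))
  q_node("not", child = query)
}

#' @rdname query
#' @export
query_active <- function(query = NULL,
                         exclude = c("negated", "historical",
                                     "other_subject", "discontinued")) {
  stopifnot(is.null(query) || inherits(query, "medex_query"))
  exclude <- match.arg(exclude, several.ok = TRUE)
  q_node("active", child = query, exclude = exclude)
}

#' @export
print.medex_query <- function(x, ...) {
  cat(deparse_query(x), "\n")
  invisible(x)
}

deparse_query <- function(q) {
  switch(q$kind,
    term = q$token,
    fuzzy = paste0("~", if (is.null(q$max_dist)) "" else q$max_dist,
                   q$token),
    phrase = paste0("\"", paste(q$tokens, collapse = " "), "\""),
    near = paste0("near/", q$slop, "(",
                  paste(q$tokens, collapse = " "), ")"),
    regex = paste0("/", q$pattern, "/"),
    and = paste0("(", paste(vapply(q$children, deparse_query,
                                   character(1)), collapse = " AND "), ")"),
    or = paste0("(", paste(vapply(q$children, deparse_query,
                                  character(1)), collapse = " OR "), ")"),
    not = paste0("NOT ", deparse_query(q$child)),
    active = paste0(
      if (is.null(q$child)) "*" else deparse_query(q$child),
      paste0(" -", q$exclude, collapse = "")
    )
  )
}

#' Parse the minimal query DSL
#'
#' Grammar: `term`, `~1term` (fuzzy, distance optional), `"a b c"`
#' (phrase), `near/1(a b c)` (proximity), `AND`/`OR`/`NOT`, parentheses,
#' and trailing exclusion flags `-negated -historical -other_subject
#' -discontinued` which wrap the whole expression in [query_active()].
#'
#' @param expr Query expression string.
#' @return A `medex_query` tree.
#' @examples
#' parse_query('~1Ibuhexal AND NOT "Aspirin forte"')
#' parse_query("near/1(Delix 5 1 0 0) -negated -discontinued")
#' @export
parse_query <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  toks <- dsl_lex(expr)
  flags <- character(0)
  keep <- logical(length(toks))
  for (i in seq_along(toks)) {
    if (grepl("^-(negated|historical|other_subject|discontinued)$",
              toks[i])) {
      flags <- c(flags, sub("^-", "", toks[i]))
    } else {
      keep[i] <- TRUE
    }
  }
  toks <- toks[keep]
  if (length(toks) == 0L) abort("empty query expression")
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  q <- dsl_or(st)
  if (st$pos <= length(st$toks)) {
    abort(sprintf("unexpected token '%s' in query", st$toks[st$pos]))
  }
  if (length(flags)) q <- query_active(q, exclude = unique(flags))
  q
}

dsl_lex <- function(expr) {
  pat <- paste0(
    '"[^"]*"',                        # phrase
    "|near/[0-9]+\\([^)]*\\)",        # proximity
    "|~[0-9]*[^\\s()]+",              # fuzzy
    "|\\(|\\)",
    "|-[a-z_]+",
    "|[^\\s()]+"
  )
  m <- gregexpr(pat, expr, perl = TRUE)[[1L]]
  if (m[1] == -1L) abort("empty query expression")
  substring(expr, m, m + attr(m, "match.length") - 1L)
}

dsl_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

dsl_or <- function(st) {
  parts <- list(dsl_and(st))
  while (identical(toupper(dsl_peek(st)), "OR")) {
    st$pos <- st$pos + 1L
    parts <- c(parts, list(dsl_and(st)))
  }
  if (length(parts) == 1L) parts[[1L]] else do.call(query_or, parts)
}

dsl_and <- function(st) {
  parts <- list(dsl_unary(st))
  repeat {
    nxt <- dsl_peek(st)
    if (is.na(nxt) || toupper(nxt) == "OR" || nxt == ")") break
    if (toupper(nxt) == "AND") st$pos <- st$pos + 1L
    parts <- c(parts, list(dsl_unary(st)))
  }
  if (length(parts) == 1L) parts[[1L]] else do.call(query_and, parts)
}

dsl_unary <- function(st) {
  tok <- dsl_peek(st)
  if (is.na(tok)) abort("unexpected end of query expression")
  if (toupper(tok) == "NOT") {
    st$pos <- st$pos + 1L
    return(query_not(dsl_unary(st)))
  }
  dsl_primary(st)
}

dsl_primary <- function(st) {
  tok <- dsl_peek(st)
  if (is.na(tok)) abort("unexpected end of query expression")
  st$pos <- st$pos + 1L
  if (tok == "(") {
    q <- dsl_or(st)
    if (!identical(dsl_peek(st), ")")) abort("missing closing parenthesis")
    st$pos <- st$pos + 1L
    return(q)
  }
  if (startsWith(tok, "\"")) {
    inner <- gsub('^"|"$', "", tok)
    return(query_phrase(strsplit(trimws(inner), "\\s+")[[1L]]))
  }
  if (grepl("^near/[0-9]+\\(", tok)) {
    slop <- as.integer(sub("^near/([0-9]+).*$", "\\1", tok))
    inner <- sub("^near/[0-9]+\\((.*)\\)$", "\\1", tok)
    return(query_near(strsplit(trimws(inner), "\\s+")[[1L]], slop = slop))
  }
  if (startsWith(tok, "~")) {
    body <- sub("^~", "", tok)
    d <- regmatches(body, regexpr("^[0-9]+", body))
    term <- sub("^[0-9]+", "", body)
    if (!nzchar(term)) abort(sprintf("malformed fuzzy token '%s'", tok))
    return(query_fuzzy(term,
                       max_dist = if (length(d) && nzchar(d))
                         as.integer(d) else NULL))
  }
  query_term(tok)
}
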