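#' Damerau-Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, substitutions
#' and adjacent transpositions converting `a` into `b`, in the optimal
#' string alignment (OSA) variant: a transposed pair is not edited again.
#' This is the metric behind the error-tolerant drug-name queries —
#' misspelled product names in manually entered reports are typically one
#' such edit away from the lexicon form (e.g. `Ibohexal` vs `Ibuhexal`).
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of pairwise distances.
#' @examples
#' dl_distance("Ibuhexal", "Ibohexal")   # 1 substitution
#' dl_distance("Ramipril", "Rampiril")   # 1 transposition
#' dl_distance("Repaglinid", "Repagilid")  # 2
#' @export
dl_distance <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  vapply(seq_len(n), function(i) osa_one(a[i], b[i]), integer(1))
}

osa_one <- function(a, b) {
  s <- utf8ToInt(a)
  t <- utf8ToInt(b)
  n <- length(s)
  m <- length(t)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev2 <- integer(m + 1L)
  prev <- 0L:m
  for (i in 1L:n) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    si <- s[i]
    for (j in 1L:m) {
      cost <- if (si == t[j]) 0L else 1L
      v <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
      if (i > 1L && j > 1L && si == t[j - 1L] && s[i - 1L] == t[j]) {
        v <- min(v, prev2[j - 1L] + 1L)
      }
      cur[j + 1L] <- v
    }
    prev2 <- prev
    prev <- cur
  }
  prev[m + 1L]
}

#' Length-dependent fuzzy matching threshold
#'
#' Default maximum edit distance per query-token length: exact matching
#' below `min_len_for_fuzzy` characters (fuzzy matching of short common
#' words is the dominant false-positive mode), one edit for lengths 5-9,
#' two edits for 10 and longer.
#'
#' @param token Character vector of query tokens.
#' @param min_len_for_fuzzy Minimum length at which fuzzy matching applies.
#' @return Integer vector of maximum distances (0, 1 or 2).
#' @export
fuzzy_max_dist <- function(token, min_len_for_fuzzy = 5L) {
  len <- nchar(token)
  ifelse(len < min_len_for_fuzzy, 0L, ifelse(len < 10L, 1L, 2L))
}

#' Expand a query token over an index vocabulary
#'
#' Returns the vocabulary tokens within `max_dist` edits (case-folded
#' comparison) of the query token.  The exact match is always included when
#' present; tokens shorter than `min_len_for_fuzzy` are matched exactly
#' only.
#'
#' @param token Single query token.
#' @param vocab Character vector of (normalized) vocabulary tokens.
#' @param max_dist Maximum Damerau-Levenshtein distance (at most 2); when
#'   `NULL` it is chosen from the token length via [fuzzy_max_dist()].
#' @param min_len_for_fuzzy Minimum token length for fuzzy matching.
#' @return Character vector of matching vocabulary tokens.
#' @export
fuzzy_expand <- function(token, vocab, max_dist = NULL,
                         min_len_for_fuzzy = 5L) {
  stopifnot(length(token) == 1L)
  tl <- tolower(token)
  if (is.null(max_dist)) {
    max_dist <- fuzzy_max_dist(tl, min_len_for_fuzzy)
  }
  stopifnot(max_dist <= 2L)
  if (length(vocab) == 0L) return(character(0))
  if (max_dist == 0L || nchar(tl) < min_len_for_fuzzy) {
    return(vocab[tolower(vocab) == tl])
  }
  vl <- tolower(vocab)
  cand <- abs(nchar(vl) - nchar(tl)) <= max_dist
  hit <- logical(length(vocab))
  if (any(cand)) {
    hit[cand] <- dl_distance(rep(tl, sum(cand)), vl[cand]) <= max_dist
  }
  hit <- hit | vl == tl
  vocab[hit]
}
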