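# Independent test oracles, deliberately written differently from the
# package implementations they check.

# full-matrix optimal-string-alignment distance, column-major fill
osa_oracle <- function(a, b) {
  s <- strsplit(a, "")[[1L]]
  t <- strsplit(b, "")[[1L]]
  n <- length(s)
  m <- length(t)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (j in seq_len(m)) {
    for (i in seq_len(n)) {
      D[i + 1L, j + 1L] <- min(
        D[i, j + 1L] + 1L,
        D[i + 1L, j] + 1L,
        D[i, j] + (s[i] != t[j])
      )
      if (i >= 2L && j >= 2L && s[i] == t[j - 1L] && s[i - 1L] == t[j]) {
        D[i + 1L, j + 1L] <- min(D[i + 1L, j + 1L], D[i - 1L, j - 1L] + 1L)
      }
    }
  }
  D[n + 1L, m + 1L]
}

# numeric value of a token string, or NA (oracle-local copy)
oracle_num <- function(x) {
  if (grepl("^[0-9]+/[0-9]+$", x)) {
    p <- as.numeric(strsplit(x, "/")[[1L]])
    if (p[1] < p[2]) return(p[1] / p[2])
    return(NA_real_)
  }
  if (grepl("^[0-9]+[.,][0-9]+$", x)) {
    return(as.numeric(sub(",", ".", x)))
  }
  if (grepl("^[0-9]+$", x)) return(as.numeric(x))
  NA_real_
}

oracle_tok_match <- function(qtok, ntok, fuzzy = FALSE, max_dist = NULL) {
  q <- tolower(qtok)
  if (q == ntok) return(TRUE)
  qv <- oracle_num(q)
  nv <- oracle_num(ntok)
  if (!is.na(qv) && !is.na(nv) && abs(qv - nv) < 1e-9) return(TRUE)
  if (!fuzzy) return(FALSE)
  d <- if (is.null(max_dist)) {
    if (nchar(q) < 5) 0L else if (nchar(q) < 10) 1L else 2L
  } else max_dist
  d > 0L && osa_oracle(q, ntok) <= d
}

# does one sentence (vector of norms + flag list) satisfy a query node?
oracle_sentence_matches <- function(q, norms, flags) {
  switch(q$kind,
    term = any(vapply(norms, oracle_tok_match, logical(1), qtok = q$token)),
    fuzzy = any(vapply(norms, oracle_tok_match, logical(1),
                       qtok = q$token, fuzzy = TRUE,
                       max_dist = q$max_dist)),
    regex = any(grepl(q$pattern, norms, perl = TRUE, ignore.case = TRUE)),
    phrase = {
      k <- length(q$tokens)
      n <- length(norms)
      ok <- FALSE
      if (n >= k) {
        for (s in 1:(n - k + 1L)) {
          if (all(vapply(seq_len(k), function(j) {
            oracle_tok_match(q$tokens[j], norms[s + j - 1L])
          }, logical(1)))) {
            ok <- TRUE
            break
          }
        }
      }
      ok
    },
    near = oracle_near(q, norms),
    and = all(vapply(q$children, oracle_sentence_matches, logical(1),
                     norms = norms, flags = flags)),
    or = any(vapply(q$children, oracle_sentence_matches, logical(1),
                    norms = norms, flags = flags)),
    not = !oracle_sentence_matches(q$child, norms, flags),
    active = {
      base <- if (is.null(q$child)) TRUE else
        oracle_sentence_matches(q$child, norms, flags)
      base && !any(unlist(flags[q$exclude]))
    },
    stop("unknown node in oracle")
  )
}

# exhaustive assignment search over all position tuples
oracle_near <- function(q, norms) {
  k <- length(q$tokens)
  opts <- lapply(q$tokens, function(tk) {
    which(vapply(norms, oracle_tok_match, logical(1), qtok = tk))
  })
  if (any(lengths(opts) == 0L)) return(FALSE)
  grid <- do.call(expand.grid, opts)
  num <- !is.na(vapply(tolower(q$tokens), oracle_num, numeric(1)))
  for (r in seq_len(nrow(grid))) {
    pos <- as.integer(grid[r, ])
    if (anyDuplicated(pos)) next
    if (max(pos) - min(pos) + 1L > k + q$slop) next
    if (isTRUE(q$ordered_numbers) && sum(num) > 1L) {
      if (is.unsorted(pos[num], strictly = TRUE)) next
    }
    return(TRUE)
  }
  FALSE
}

# evaluate a query over a sentence list by brute-force scan
oracle_execute <- function(q, sents) {
  hits <- vapply(sents, function(s) {
    oracle_sentence_matches(q, s$norms, s$flags)
  }, logical(1))
  names(sents)[hits]
}
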