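#' Default dosing-pattern catalog
#'
#' Dose queries are expanded into one proximity disjunct per dosing
#' pattern with the requested daily-unit sum.  The catalog enumerates all
#' three-slot (morning-noon-evening) patterns over the per-slot alphabet
#' {0, 1/4, 1/2, 1, 2} whose sums are the daily-unit values seen in
#' practice: 0.25, 0.5, 1, 1.5, 2, 3 and 4.  It is configuration data —
#' extend it for four-slot schedules or unusual splits.
#'
#' @return A named list: daily-unit value (as character, e.g. `"1"`,
#'   `"0.5"`) to a list of numeric pattern vectors.
#' @export
default_pattern_catalog <- function() {
  slots <- c(0, 0.25, 0.5, 1, 2)
  grid <- expand.grid(m = slots, n = slots, e = slots)
  sums <- grid$m + grid$n + grid$e
  keep <- sums %in% c(0.25, 0.5, 1, 1.5, 2, 3, 4)
  grid <- grid[keep, , drop = FALSE]
  sums <- sums[keep]
  out <- list()
  for (u in sort(unique(sums))) {
    rows <- which(sums == u)
    out[[format(u)]] <- lapply(rows, function(r) {
      as.numeric(grid[r, ])
    })
  }
  out
}

# per-slot values that can occur in a dosing pattern; large numbers are
# strengths, not schedule slots
pattern_alphabet <- function() {
  c(0, 0.25, 1 / 3, 0.5, 0.75, 1, 1.5, 2, 3, 4)
}

is_pattern_value <- function(v) {
  !is.na(v) & vapply(v, function(x) {
    any(abs(x - pattern_alphabet()) < 1e-9)
  }, logical(1))
}

#' Parse strength and dosing pattern from an instruction sentence
#'
#' Recovers the two components of a daily dose from the tokens following
#' a matched drug name: the strength (first number directly followed by a
#' unit token, starting within `max_gap` tokens of the drug name) and the
#' dosing pattern (first run of 3 or 4 consecutive schedule numbers, such
#' as `1-0-0` or `1/2-0-1/2`, skipping the strength pair and at most
#' `pattern_gap` intervening tokens).  Either component may be absent;
#' absence is a value, not an error.  Schedule slots are restricted to
#' plausible per-slot amounts, so a strength written in pattern position
#' (`"150-0-150 mg"`) is not misread as a schedule.
#'
#' @param tokens Token tibble of one sentence (from [tokenize()] or a
#'   sentence's rows of [tokenize_sentences()]).
#' @param drug_end 0-based index of the last token of the drug name.
#' @param max_gap Maximum tokens between drug name and strength number.
#' @param pattern_gap Maximum tokens skipped between strength (or drug)
#'   and the dosing pattern (parenthetical supplements).
#' @return A one-row tibble: `strength`, `unit`, `pattern` (list column),
#'   `daily_units`, `daily_dose` (`NA` where a component is absent).
#' @export
parse_dose_instruction <- function(tokens, drug_end, max_gap = 2L,
                                   pattern_gap = 4L) {
  stopifnot(nrow(tokens) >= 1L)
  r <- parse_dose_core(tokens$idx, tokens$kind, tokens$value,
                       tokens$norm, drug_end, max_gap, pattern_gap)
  tibble(
    strength = r$strength, unit = r$unit, pattern = list(r$pattern),
    daily_units = r$daily_units, daily_dose = r$daily_dose
  )
}

parse_dose_core <- function(idx, kind, value, norm, drug_end,
                            max_gap = 2L, pattern_gap = 4L) {
  absent <- list(strength = NA_real_, unit = NA_character_,
                 pattern = NULL, daily_units = NA_real_,
                 daily_dose = NA_real_)
  keep <- idx > drug_end
  if (!any(keep)) return(absent)
  ord <- order(idx[keep])
  after <- list(idx = idx[keep][ord], kind = kind[keep][ord],
                value = value[keep][ord], norm = norm[keep][ord])
  n <- length(after$idx)

  numericish <- after$kind %in% c("integer", "decimal", "fraction")
  strength <- NA_real_
  unit <- NA_character_
  strength_rows <- integer(0)
  for (i in seq_len(min(max_gap + 1L, n))) {
    if (numericish[i] && i < n && after$kind[i + 1L] == "unit") {
      strength <- after$value[i]
      unit <- after$norm[i + 1L]
      strength_rows <- c(i, i + 1L)
      break
    }
  }

  # first run of 3-4 consecutive schedule tokens after the strength pair
  search_from <- if (length(strength_rows)) max(strength_rows) + 1L else 1L
  pattern <- NULL
  i <- search_from
  while (i <= n) {
    if (length(strength_rows) &&
        i - max(strength_rows) - 1L > pattern_gap) break
    if (!length(strength_rows) && i - 1L > max_gap + pattern_gap) break
    if (numericish[i] && is_pattern_value(after$value[i]) &&
        !(i %in% strength_rows)) {
      j <- i
      while (j < n && numericish[j + 1L] &&
             after$idx[j + 1L] == after$idx[j] + 1L &&
             is_pattern_value(after$value[j + 1L])) {
        j <- j + 1L
      }
      run_len <- j - i + 1L
      if (run_len %in% c(3L, 4L)) {
        pattern <- after$value[i:j]
        break
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }

  daily_units <- if (is.null(pattern)) NA_real_ else sum(pattern)
  list(
    strength = strength, unit = unit, pattern = pattern,
    daily_units = daily_units,
    daily_dose = if (!is.na(strength) && !is.na(daily_units)) {
      strength * daily_units
    } else NA_real_
  )
}

#' Daily dose from strength and dosing pattern
#'
#' The daily dose is the sum of the 3 or 4 schedule numbers (morning,
#' noon, evening, optionally night) multiplied by the strength.
#'
#' @param s Strength (positive number, in the strength unit).
#' @param d Numeric dosing pattern of length 3 or 4.
#' @return `s * sum(d)`.
#' @examples
#' compute_daily_dose(5, c(1, 0, 1))      # 10
#' compute_daily_dose(110, c(1, 0, 1))    # 220
#' @export
compute_daily_dose <- function(s, d) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0)
  if (!length(d) %in% c(3L, 4L)) {
    abort(sprintf("dosing pattern must have 3 or 4 numbers, got %d",
                  length(d)))
  }
  stopifnot(all(d >= 0))
  s * sum(d)
}

format_num_token <- function(v) {
  vapply(v, function(x) {
    if (abs(x - round(x)) < 1e-9) return(format(round(x)))
    if (abs(x - 0.5) < 1e-9) return("1/2")
    if (abs(x - 0.25) < 1e-9) return("1/4")
    if (abs(x - 0.75) < 1e-9) return("3/4")
    sub(".", ",", format(x), fixed = TRUE)
  }, character(1))
}

#' Expand a daily-dose query into proximity disjuncts
#'
#' Builds the OR-of-proximity query that finds instructions of a drug at
#' a given strength and daily-unit total: one [query_near()] node per
#' dosing pattern in the catalog with that sum, each over the drug
#' tokens, the strength number and the pattern numbers.
#'
#' @param drug_tokens Character vector of drug-name tokens.
#' @param strength Strength number (e.g. 5 for "5 mg").
#' @param daily_units Requested daily-unit total (must be a catalog key).
#' @param catalog Pattern catalog, see [default_pattern_catalog()].
#' @param slop Proximity slop per disjunct (default 1 tolerates the unit
#'   token between strength and schedule).
#' @return A `medex_query` (an `or` over `near` nodes).
#' @examples
#' expand_dose_query(c("Delix"), 5, 1)
#' @export
expand_dose_query <- function(drug_tokens, strength, daily_units,
                              catalog = default_pattern_catalog(),
                              slop = 1L) {
  stopifnot(is.character(drug_tokens), length(drug_tokens) >= 1L)
  key <- format(daily_units)
  pats <- catalog[[key]]
  if (is.null(pats) || length(pats) == 0L) {
    abort(sprintf(
      "no dosing patterns for daily_units = %s; catalog has: %s",
      key, paste(names(catalog), collapse = ", ")
    ))
  }
  nodes <- lapply(pats, function(p) {
    query_near(
      c(drug_tokens, format_num_token(strength), format_num_token(p)),
      slop = slop, ordered_numbers = TRUE
    )
  })
  do.call(query_or, nodes)
}

#' Aggregate parsed doses into a dose distribution
#'
#' Tabulates the joint distribution of daily units and strength over
#' non-discontinued instructions of one drug — the per-drug dose profile
#' from which the average daily dose is computed.
#'
#' @param doses A tibble with columns `daily_units`, `strength`, `unit`
#'   and optionally `discontinued` (discontinued rows are excluded).
#' @param drug Label for the drug (attached as attribute).
#' @return A tibble of class `medex_dose_distribution` with columns
#'   `daily_units`, `strength`, `unit`, `n`, `proportion`.
#' @export
aggregate_dose_distribution <- function(doses, drug = NA_character_) {
  stopifnot(all(c("daily_units", "strength") %in% names(doses)))
  if (!"discontinued" %in% names(doses)) doses$discontinued <- FALSE
  if (!"unit" %in% names(doses)) doses$unit <- NA_character_
  d <- doses %>%
    filter(!discontinued, !is.na(daily_units), !is.na(strength))
  out <- d %>%
    count(daily_units, strength, unit, name = "n") %>%
    mutate(proportion = n / sum(n)) %>%
    arrange(daily_units, strength)
  structure(out, class = c("medex_dose_distribution", class(out)),
            drug = drug)
}

#' Proportion-weighted average daily dose
#'
#' `sum(p * u * s) / sum(p)` over the distribution cells — the mean daily
#' dose in the strength unit of the distribution.
#'
#' @param dist A dose distribution: a tibble with `daily_units`,
#'   `strength`, `proportion` (from [aggregate_dose_distribution()] or
#'   assembled directly from published percentages).
#' @return The average daily dose (single number).
#' @export
average_daily_dose <- function(dist) {
  stopifnot(all(c("daily_units", "strength", "proportion") %in%
                  names(dist)))
  if (nrow(dist) == 0L || sum(dist$proportion) <= 0) {
    abort("empty dose distribution")
  }
  stopifnot(all(dist$proportion >= 0))
  sum(dist$proportion * dist$daily_units * dist$strength) /
    sum(dist$proportion)
}
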