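#' Construct a cohort filter
#'
#' In-/exclusion criteria replicating published study cohorts: ICD-10
#' prefix lists, a half-open discharge-date range, an inclusive age range
#' and an optional sex restriction.  A case passes when at least one of
#' its ICD codes matches an include prefix (if any are given), no code
#' matches an exclude prefix, and its discharge date, age and sex fall in
#' range.
#'
#' @param include_icd,exclude_icd Character vectors of ICD-10 code
#'   prefixes (e.g. `"I48"`); may be empty.
#' @param date_start,date_end Discharge-date range `[date_start,
#'   date_end)`; `NULL` for unbounded.
#' @param age_min,age_max Inclusive age bounds.
#' @param sex Optional `"m"` or `"f"`.
#' @return A list of class `medex_cohort_filter`.
#' @export
cohort_filter <- function(include_icd = character(0),
                          exclude_icd = character(0),
                          date_start = NULL, date_end = NULL,
                          age_min = 0L, age_max = 150L, sex = NULL) {
  icd_ok <- function(p) grepl("^[A-Z][0-9]{0,2}(\\.[0-9]{1,2})?$", p)
  bad <- c(include_icd[!icd_ok(include_icd)],
           exclude_icd[!icd_ok(exclude_icd)])
  if (length(bad)) {
    abort(sprintf("malformed ICD prefix(es): %s",
                  paste(bad, collapse = ", ")))
  }
  if (!is.null(date_start)) date_start <- as.Date(date_start)
  if (!is.null(date_end)) date_end <- as.Date(date_end)
  if (!is.null(date_start) && !is.null(date_end)) {
    stopifnot(date_start <= date_end)
  }
  stopifnot(age_min <= age_max)
  structure(
    list(include_icd = include_icd, exclude_icd = exclude_icd,
         date_start = date_start, date_end = date_end,
         age_min = age_min, age_max = age_max, sex = sex),
    class = "medex_cohort_filter"
  )
}

#' Apply a cohort filter to a corpus
#'
#' @param docs Document tibble with `icd_codes` (list column),
#'   `discharge_date`, `age_years`, `sex`.
#' @param filter A [cohort_filter()].
#' @return The subset of `docs` passing the criteria.
#' @export
apply_cohort_filter <- function(docs, filter) {
  stopifnot(inherits(filter, "medex_cohort_filter"))
  matches_any <- function(codes, prefixes) {
    if (length(prefixes) == 0L) return(FALSE)
    any(vapply(prefixes, function(p) any(startsWith(codes, p)),
               logical(1)))
  }
  keep <- vapply(seq_len(nrow(docs)), function(i) {
    codes <- docs$icd_codes[[i]]
    if (is.null(codes)) codes <- character(0)
    if (length(filter$include_icd) &&
        !matches_any(codes, filter$include_icd)) return(FALSE)
    if (matches_any(codes, filter$exclude_icd)) return(FALSE)
    d <- as.Date(docs$discharge_date[i])
    if (!is.null(filter$date_start) && d < filter$date_start) return(FALSE)
    if (!is.null(filter$date_end) && d >= filter$date_end) return(FALSE)
    a <- docs$age_years[i]
    if (a < filter$age_min || a > filter$age_max) return(FALSE)
    if (!is.null(filter$sex) && !identical(docs$sex[i], filter$sex)) {
      return(FALSE)
    }
    TRUE
  }, logical(1))
  docs[keep, , drop = FALSE]
}

#' Medication-prevalence trend table
#'
#' For each period (half-open on discharge date) and each ATC drug group,
#' counts the cases with at least one currently-valid mention of any of
#' the group's query terms — a Boolean is-the-drug-taken extraction — and
#' reports the prevalence percentage.  A case mentioning several drugs of
#' one group counts once.
#'
#' @param docs Case tibble (typically after [apply_cohort_filter()]).
#' @param mentions Mention tibble from [find_drug_mentions()] /
#'   [extract_medications()]; only active mentions should be passed.
#' @param groups Tibble with columns `label`, `atc_prefix`.
#' @param periods Tibble with columns `label`, `start`, `end`
#'   (half-open date ranges).
#' @param per_patient Count distinct patients instead of cases.
#' @return A tibble of class `medex_trend`: `period_label`, `group_label`,
#'   `n_cases`, `n_with`, `percent`, `undefined` (true where a period has
#'   no cases and the percentage is reported as 0).
#' @export
drug_prevalence_trend <- function(docs, mentions, groups, periods,
                                  per_patient = FALSE) {
  stopifnot(all(c("label", "atc_prefix") %in% names(groups)),
            all(c("label", "start", "end") %in% names(periods)))
  if (any(!nzchar(groups$atc_prefix))) abort("empty ATC prefix in groups")
  ps <- as.Date(periods$start)
  pe <- as.Date(periods$end)
  if (nrow(periods) > 1L) {
    ov <- any(vapply(2:nrow(periods), function(i) {
      any(ps[i] < pe[1:(i - 1)] & pe[i] > ps[1:(i - 1)])
    }, logical(1)))
    if (ov) warn("trend periods overlap; cases are counted in each")
  }
  id_col <- if (per_patient) "patient_id" else "case_id"
  if (!id_col %in% names(docs)) id_col <- "doc_id"
  dd <- as.Date(docs$discharge_date)
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(periods))) {
    in_period <- !is.na(dd) & dd >= ps[i] & dd < pe[i]
    period_docs <- docs[in_period, , drop = FALSE]
    n_cases <- dplyr::n_distinct(period_docs[[id_col]])
    for (g in seq_len(nrow(groups))) {
      m <- mentions[mentions$doc_id %in% period_docs$doc_id &
                      startsWith(mentions$atc_code,
                                 groups$atc_prefix[g]), , drop = FALSE]
      with_ids <- period_docs[[id_col]][period_docs$doc_id %in% m$doc_id]
      n_with <- dplyr::n_distinct(with_ids)
      k <- k + 1L
      rows[[k]] <- tibble(
        period_label = periods$label[i],
        group_label = groups$label[g],
        n_cases = n_cases, n_with = n_with,
        percent = if (n_cases > 0L) 100 * n_with / n_cases else 0,
        undefined = n_cases == 0L
      )
    }
  }
  out <- bind_rows(rows)
  structure(out, class = c("medex_trend", class(out)))
}

#' Extract values of a numeric concept
#'
#' Finds occurrences of the concept terms in the indexed sentences and
#' takes the first numeric token within `window` tokens after the concept
#' as its value — e.g. 135 from `"RR 135/80 mmHg"` for concept `"RR"`.
#'
#' @param index A `medex_index`.
#' @param concept_terms Character vector of concept tokens (any matches).
#' @param window Token window after the concept match.
#' @return A tibble `doc_id`, `sentence_id`, `value`.
#' @export
extract_numeric_concept <- function(index, concept_terms, window = 3L) {
  stopifnot(inherits(index, "medex_index"), length(concept_terms) >= 1L)
  terms <- tolower(concept_terms)
  post <- index$postings
  hits <- post[post$norm %in% terms, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble(doc_id = character(0), sentence_id = character(0),
                  value = numeric(0)))
  }
  rows <- purrr::map(seq_len(nrow(hits)), function(i) {
    sid <- hits$sentence_id[i]
    st <- index$sent_tokens[[sid]]
    cand <- which(st$idx > hits$idx[i] &
                    st$idx <= hits$idx[i] + window & !is.na(st$value))
    if (length(cand) == 0L) return(NULL)
    tibble(doc_id = hits$doc_id[i], sentence_id = sid,
           value = st$value[cand[1L]])
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(doc_id = character(0), sentence_id = character(0),
                  value = numeric(0)))
  }
  out
}

#' Bin values into half-open groups
#'
#' Partitions values into `(-Inf, e1), [e1, e2), ..., [ek, Inf)` for
#' ordered bin edges `e1 < ... < ek` and reports counts and percentages
#' (summing to 100 up to rounding).
#'
#' @param values Numeric vector.
#' @param edges Strictly increasing numeric vector of bin boundaries.
#' @return A tibble `bin`, `n`, `percent`; empty values give zero rows
#'   with a warning.
#' @export
group_values <- function(values, edges) {
  stopifnot(is.numeric(edges), length(edges) >= 1L,
            all(diff(edges) > 0))
  labels <- c(
    sprintf("<%s", format(edges[1])),
    if (length(edges) > 1L) {
      sprintf("[%s-%s)", format(edges[-length(edges)]),
              format(edges[-1]))
    },
    sprintf(">=%s", format(edges[length(edges)]))
  )
  if (length(values) == 0L) {
    warn("no values to bin")
    return(tibble(bin = labels, n = 0L, percent = NA_real_))
  }
  idx <- findInterval(values, edges) + 1L
  n <- vapply(seq_along(labels), function(b) sum(idx == b), integer(1))
  tibble(bin = labels, n = n, percent = 100 * n / length(values))
}
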