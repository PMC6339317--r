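#' Read a discharge-letter corpus from JSON lines
#'
#' One JSON object per line with fields `doc_id`, `patient_id`, `case_id`,
#' `admission_date`, `discharge_date` (ISO-8601), `age_years`, `sex`
#' (`"m"`, `"f"` or `"u"`), `icd_codes` (array of ICD-10 strings) and
#' `text`.
#'
#' @param path Path to the `.jsonl` file (UTF-8).
#' @return A tibble with one row per case; `icd_codes` is a list column,
#'   dates are `Date`.
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) abort(sprintf("corpus file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(lines, function(l) {
    jsonlite::fromJSON(l, simplifyVector = TRUE)
  })
  docs <- tibble(
    doc_id = purrr::map_chr(recs, "doc_id"),
    patient_id = purrr::map_chr(recs, "patient_id",
                                .default = NA_character_),
    case_id = purrr::map_chr(recs, "case_id", .default = NA_character_),
    admission_date = as.Date(purrr::map_chr(recs, "admission_date",
                                            .default = NA_character_)),
    discharge_date = as.Date(purrr::map_chr(recs, "discharge_date",
                                            .default = NA_character_)),
    age_years = purrr::map_int(recs, function(r) {
      as.integer(r$age_years %||% NA_integer_)
    }),
    sex = purrr::map_chr(recs, "sex", .default = "u"),
    icd_codes = purrr::map(recs, function(r) {
      as.character(r$icd_codes %||% character(0))
    }),
    text = purrr::map_chr(recs, "text", .default = "")
  )
  bad <- !is.na(docs$admission_date) & !is.na(docs$discharge_date) &
    docs$admission_date > docs$discharge_date
  if (any(bad)) {
    abort(sprintf("admission after discharge in doc(s): %s",
                  paste(docs$doc_id[bad], collapse = ", ")))
  }
  docs
}

#' Write a corpus tibble as JSON lines
#'
#' @param docs Document tibble as returned by [read_corpus_jsonl()] or
#'   [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(docs, path) {
  lines <- vapply(seq_len(nrow(docs)), function(i) {
    jsonlite::toJSON(
      list(
        doc_id = docs$doc_id[i],
        patient_id = docs$patient_id[i],
        case_id = docs$case_id[i],
        admission_date = format(docs$admission_date[i]),
        discharge_date = format(docs$discharge_date[i]),
        age_years = docs$age_years[i],
        sex = docs$sex[i],
        icd_codes = docs$icd_codes[[i]],
        text = docs$text[i]
      ),
      auto_unbox = TRUE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
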