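#' Index a corpus end to end
#'
#' Convenience wrapper chaining section splitting, instruction
#' segmentation, tokenization and context annotation into a ready-to-query
#' positional index.
#'
#' @param docs Corpus tibble ([read_corpus_jsonl()] or
#'   [generate_corpus()]`$docs`).
#' @param headers Section-header lexicon.
#' @param triggers ConText trigger lexicon.
#' @param include Which sentence sources to index: `"medication"`
#'   sections (instruction-segmented) and/or `"lines"` (other sections,
#'   line-wise).
#' @return A list with `index` (`medex_index`), `sections`, `sentences`,
#'   `tokens`, and a `counts` tibble of per-stage sizes.
#' @export
build_corpus_index <- function(docs,
                               headers = default_section_headers(),
                               triggers = default_trigger_lexicon(),
                               include = "medication") {
  sections <- split_sections(docs, headers)
  sentences <- bind_rows(
    if ("medication" %in% include) segment_instructions(sections),
    if ("lines" %in% include) segment_lines(sections)
  )
  if (is.null(sentences) || nrow(sentences) == 0L) {
    sentences <- empty_sentence_tbl()
  }
  tokens <- tokenize_sentences(sentences)
  tokens <- annotate_context(tokens, triggers, sentences = sentences)
  index <- build_index(sentences, tokens)
  active <- filter_active(sentences, tokens)
  counts <- tibble(
    stage = c("documents", "sections", "sentences", "active_sentences",
              "filtered_sentences", "tokens"),
    n = c(nrow(docs), nrow(sections), nrow(sentences), nrow(active),
          nrow(sentences) - nrow(active), nrow(tokens))
  )
  list(index = index, sections = sections, sentences = sentences,
       tokens = tokens, counts = counts)
}

#' Run the full extraction pipeline
#'
#' Orchestrates the stages index, context filter, mention extraction,
#' dose parsing and (optionally) trend aggregation, writing each artifact
#' to `out_dir`: `medications.csv`, `counts.csv`, and `trend.csv` when a
#' study configuration is given.
#'
#' @param corpus Path to a JSONL corpus or a corpus tibble.
#' @param drug_db Path to a drug-lexicon TSV or a lexicon tibble.
#' @param out_dir Output directory (created if missing).
#' @param study Optional study configuration: a YAML path or a list with
#'   elements `filter` (arguments to [cohort_filter()]), `groups`
#'   (`label`, `atc_prefix`) and `periods` (`label`, `start`, `end`).
#' @param fuzzy Enable error-tolerant matching.
#' @param headers,triggers Lexicons, as in [build_corpus_index()].
#' @return Invisibly, a list with `medications`, `trend` (or `NULL`),
#'   `counts` and the artifact paths.
#' @export
run_pipeline <- function(corpus, drug_db = default_drug_db(),
                         out_dir = ".", study = NULL, fuzzy = TRUE,
                         headers = default_section_headers(),
                         triggers = default_trigger_lexicon()) {
  docs <- if (is.character(corpus)) read_corpus_jsonl(corpus) else corpus
  db <- if (is.character(drug_db)) read_drug_db(drug_db) else drug_db
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  built <- build_corpus_index(docs, headers = headers,
                              triggers = triggers)
  meds <- extract_medications(built$index, db, fuzzy = fuzzy)
  meds <- mention_doc_spans(meds, built$sentences)

  med_path <- file.path(out_dir, "medications.csv")
  flat <- meds
  flat$pattern <- vapply(flat$pattern, function(p) {
    if (is.null(p)) "" else paste(format_num_token(p), collapse = "-")
  }, character(1))
  utils::write.csv(flat, med_path, row.names = FALSE, fileEncoding =
                     "UTF-8")
  counts_path <- file.path(out_dir, "counts.csv")
  utils::write.csv(built$counts, counts_path, row.names = FALSE)

  trend <- NULL
  trend_path <- NULL
  if (!is.null(study)) {
    if (is.character(study)) study <- yaml::read_yaml(study)
    cohort <- apply_cohort_filter(docs,
                                  do.call(cohort_filter, study$filter))
    groups <- bind_rows(study$groups)
    periods <- bind_rows(study$periods)
    trend <- drug_prevalence_trend(
      cohort, meds[meds$doc_id %in% cohort$doc_id, , drop = FALSE],
      groups, periods
    )
    trend_path <- file.path(out_dir, "trend.csv")
    utils::write.csv(trend, trend_path, row.names = FALSE)
  }
  invisible(list(
    medications = meds, trend = trend, counts = built$counts,
    paths = c(medications = med_path, counts = counts_path,
              trend = trend_path)
  ))
}
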