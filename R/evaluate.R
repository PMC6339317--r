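#' Compare extracted medications against a gold standard
#'
#' Greedy one-to-one matching: a prediction is a true positive when an
#' unmatched gold record of the same document and canonical drug
#' (case-insensitive) has an overlapping character span.  Each gold item
#' is matched at most once; unmatched predictions are false positives and
#' unmatched gold items false negatives.  Precision is reported as 0 when
#' there are no predictions.
#'
#' @param pred Prediction tibble with `doc_id`, `canonical` and
#'   document-level spans `doc_start`, `doc_end` (as produced by
#'   [extract_medications()] after [mention_doc_spans()]).
#' @param gold Gold tibble with `doc_id`, `canonical`, `start`, `end`
#'   (from [generate_corpus()]); filter it to the relevant subset (e.g.
#'   active medication) before calling.
#' @param by Optional name of a column present in both tables to also
#'   report per-subgroup metrics (e.g. a period or ICD stratum).
#' @return An object of class `medex_eval`; see [tidy.medex_eval()].
#' @export
evaluate_extraction <- function(pred, gold, by = NULL) {
  stopifnot(all(c("doc_id", "canonical", "doc_start", "doc_end") %in%
                  names(pred)),
            all(c("doc_id", "canonical", "start", "end") %in%
                  names(gold)))
  gold$gold_id <- seq_len(max(nrow(gold), 0L))
  pred$pred_id <- seq_len(max(nrow(pred), 0L))
  matched_gold <- integer(0)
  tp_rows <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cand <- which(
      gold$doc_id == pred$doc_id[i] &
        tolower(gold$canonical) == tolower(pred$canonical[i]) &
        gold$start < pred$doc_end[i] &
        gold$end > pred$doc_start[i] &
        !(gold$gold_id %in% matched_gold)
    )
    if (length(cand)) {
      matched_gold <- c(matched_gold, gold$gold_id[cand[1L]])
      tp_rows[i] <- TRUE
    }
  }
  counts <- function(p_idx, g_idx) {
    tp <- sum(tp_rows[p_idx])
    fp <- sum(!tp_rows[p_idx])
    fn <- sum(!(gold$gold_id[g_idx] %in% matched_gold))
    metric_row(tp, fp, fn)
  }
  overall <- counts(seq_len(nrow(pred)), seq_len(nrow(gold)))
  overall$dataset <- "overall"
  per_group <- NULL
  if (!is.null(by)) {
    stopifnot(by %in% names(pred), by %in% names(gold))
    vals <- sort(unique(c(pred[[by]], gold[[by]])))
    per_group <- bind_rows(lapply(vals, function(v) {
      r <- counts(which(pred[[by]] == v), which(gold[[by]] == v))
      r$dataset <- as.character(v)
      r
    }))
  }
  structure(
    list(metrics = bind_rows(overall, per_group),
         tp_rows = tp_rows, matched_gold = matched_gold,
         n_pred = nrow(pred), n_gold = nrow(gold)),
    class = "medex_eval"
  )
}

metric_row <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0L) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble(TP = tp, FP = fp, FN = fn,
         precision = precision, recall = recall, F1 = f1)
}

#' @export
print.medex_eval <- function(x, ...) {
  cat("<medex_eval>\n")
  print(as_tibble(x$metrics))
  invisible(x)
}

#' Tidy an extraction evaluation
#'
#' @param x A `medex_eval` from [evaluate_extraction()].
#' @param ... Unused.
#' @return A tibble with `dataset`, `TP`, `FP`, `FN`, `precision`,
#'   `recall`, `F1`.
#' @export
tidy.medex_eval <- function(x, ...) {
  x$metrics[, c("dataset", "TP", "FP", "FN", "precision", "recall",
                "F1")]
}

#' @method glance medex_eval
#' @export
glance.medex_eval <- function(x, ...) {
  ov <- x$metrics[x$metrics$dataset == "overall", ]
  tibble(n_pred = x$n_pred, n_gold = x$n_gold,
         precision = ov$precision, recall = ov$recall, F1 = ov$F1)
}

#' Summarise an index
#'
#' @param x A `medex_index`.
#' @param ... Unused.
#' @return One-row tibble with document, sentence, posting and vocabulary
#'   counts.
#' @method glance medex_index
#' @export
glance.medex_index <- function(x, ...) {
  tibble(
    n_docs = dplyr::n_distinct(x$sentences$doc_id),
    n_sentences = nrow(x$sentences),
    n_postings = nrow(x$postings),
    n_vocab = length(x$vocab)
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Convert sentence-local mention spans to document offsets
#'
#' @param mentions Mention/medication tibble with `sentence_id`, `start`,
#'   `end` columns local to the sentence.
#' @param sentences Sentence tibble with document-level `start` offsets.
#' @return `mentions` with added `doc_start`, `doc_end` columns.
#' @export
mention_doc_spans <- function(mentions, sentences) {
  ord <- match(mentions$sentence_id, sentences$sentence_id)
  mentions$doc_start <- sentences$start[ord] + mentions$start
  mentions$doc_end <- sentences$start[ord] + mentions$end
  mentions
}
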