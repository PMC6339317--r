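#' Default stoplists for drug-name normalization
#'
#' Modifier words (effect or administration-form qualifiers such as
#' "forte", "akut", "retard", "oral") and manufacturer names that are
#' stripped from product names when generating query terms.  Both lists
#' are open-ended configuration: the shipped defaults cover the common
#' German market forms.
#'
#' @return Character vector of stop tokens (case-insensitive).
#' @export
default_modifier_stoplist <- function() {
  c("forte", "akut", "retard", "oral", "mite", "plus", "n",
    "hustenlöser", "brausetabletten", "tabletten", "kapseln",
    "saft", "tropfen", "salbe", "filmtabletten", "uno", "comp",
    "depot", "zok")
}

#' @rdname default_modifier_stoplist
#' @export
default_manufacturer_stoplist <- function() {
  c("bayer", "ratiopharm", "hexal", "stada", "al", "abz", "verla",
    "sandoz", "1a", "pharma", "ct", "dura", "heumann")
}

#' Normalize a drug product name into query tokens
#'
#' Simplifies a lexicon product name the way reports mention drugs:
#' strength-and-unit pairs (`"100mg"`), standalone numbers, manufacturer
#' names and modifier words are removed; hyphens disappear in
#' tokenization; remaining token order is preserved.  A non-empty input
#' never yields an empty result — if everything is stripped, the first
#' token is kept.
#'
#' @param product_name Character vector of product names.
#' @param modifiers,manufacturers Stop token vectors (case-insensitive).
#' @return A list of character vectors (one token sequence per input).
#' @examples
#' normalize_drug_name("Bayer Aspirin forte 100mg")   # "Aspirin"
#' normalize_drug_name("Paracetamol-Ratiopharm 500mg")
#' @export
normalize_drug_name <- function(product_name,
                                modifiers = default_modifier_stoplist(),
                                manufacturers =
                                  default_manufacturer_stoplist()) {
  stopifnot(is.character(product_name))
  stop_all <- tolower(c(modifiers, manufacturers))
  purrr::map(product_name, function(nm) {
    tok <- tokenize(nm)
    if (nrow(tok) == 0L) return(character(0))
    numeric_kind <- tok$kind %in% c("integer", "decimal", "fraction")
    drop <- numeric_kind |
      tok$kind == "unit" |
      tok$norm %in% stop_all
    kept <- tok$surface[!drop]
    if (length(kept) == 0L) kept <- tok$surface[1L]
    kept
  })
}

atc_pattern <- function() {
  "^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$"
}

#' Read a drug lexicon from TSV
#'
#' The lexicon stands in for a licensed drug database export.  Schema
#' (tab-separated): `product_name`, `atc_code`, `alt_names` (`|`-separated
#' alternative names or abbreviations, may be empty), and optionally
#' `strengths` (`|`-separated numbers, decimal point) and `unit` used by
#' the synthetic generator.  Rows with a syntactically invalid ATC code are rejected
#' with their line number.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `product_name`, `atc_code`, `processed`
#'   (list of token sequences from [normalize_drug_name()]), `alt` (list
#'   of lists of token sequences), `strengths` (list of numeric vectors)
#'   and `unit`.
#' @export
read_drug_db <- function(path) {
  if (!file.exists(path)) abort(sprintf("drug db file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "#",
                          fileEncoding = "UTF-8")
  stopifnot(all(c("product_name", "atc_code") %in% names(df)))
  bad <- !grepl(atc_pattern(), df$atc_code)
  if (any(bad)) {
    abort(sprintf("invalid ATC code(s) at line(s) %s: %s",
                  paste(which(bad) + 1L, collapse = ", "),
                  paste(df$atc_code[bad], collapse = ", ")))
  }
  if (is.null(df$alt_names)) df$alt_names <- ""
  alt <- purrr::map(df$alt_names, function(a) {
    if (is.na(a) || !nzchar(a)) return(list())
    purrr::map(strsplit(a, "|", fixed = TRUE)[[1L]], function(x) {
      tokenize(trimws(x))$surface
    })
  })
  strengths <- if (is.null(df$strengths)) {
    rep(list(numeric(0)), nrow(df))
  } else {
    purrr::map(df$strengths, function(s) {
      if (is.na(s) || !nzchar(s)) return(numeric(0))
      as.numeric(strsplit(as.character(s), "|", fixed = TRUE)[[1L]])
    })
  }
  tibble(
    product_name = df$product_name,
    atc_code = df$atc_code,
    processed = normalize_drug_name(df$product_name),
    alt = alt,
    strengths = strengths,
    unit = if (is.null(df$unit)) "mg" else
      ifelse(is.na(df$unit) | !nzchar(df$unit), "mg", df$unit)
  )
}

#' Bundled demonstration drug lexicon
#'
#' A small open lexicon covering the ATC groups of the shipped designation
#' maps plus the drugs used in the worked examples (Esidrix, Concor,
#' Delix, Xarelto, Eliquis, Pradaxa, ...).  It is a synthetic stand-in for
#' a licensed drug database: drop in a full export with the same TSV
#' schema for production use.
#'
#' @return Drug lexicon tibble, see [read_drug_db()].
#' @export
default_drug_db <- function() {
  read_drug_db(system.file("extdata", "drug_db.tsv", package = "medtrawl"))
}

#' Query terms of an ATC group
#'
#' Collects all processed product names and alternative names of lexicon
#' entries whose ATC code starts with the given prefix (e.g. `"C07"` for
#' beta blocking agents), deduplicated after case folding.
#'
#' @param atc_prefix ATC code prefix (1-7 characters).
#' @param db Drug lexicon tibble from [read_drug_db()].
#' @return A tibble with columns `term` (display form) and `tokens` (list
#'   of token vectors).  Empty, with a warning, for a prefix matching no
#'   entry.
#' @export
build_query_terms <- function(atc_prefix, db) {
  stopifnot(is.character(atc_prefix), length(atc_prefix) == 1L)
  hit <- nzchar(atc_prefix) & startsWith(db$atc_code, atc_prefix)
  if (!any(hit)) {
    warn(sprintf("no lexicon entry with ATC prefix '%s'", atc_prefix))
    return(tibble(term = character(0), tokens = list()))
  }
  seqs <- c(db$processed[hit],
            unlist(db$alt[hit], recursive = FALSE))
  seqs <- seqs[lengths(seqs) > 0L]
  key <- vapply(seqs, function(s) paste(tolower(s), collapse = " "),
                character(1))
  keep <- !duplicated(key)
  tibble(
    term = vapply(seqs[keep], paste, character(1), collapse = " "),
    tokens = seqs[keep]
  )
}

#' Read a designation map (drug groups to ATC, diagnoses to ICD-10)
#'
#' Maps group designations as used in the drug-utilization literature to
#' code prefixes, e.g. "Beta blockers" to `C07` or "Atrial fibrillation"
#' to `I48`.  Schema (tab-separated): `designation`, `codes`
#' (`|`-separated prefixes), optional `abbr`.
#'
#' @param path Path to the TSV file.
#' @param kind `"atc"` or `"icd"`; controls code validation.
#' @return A tibble with columns `designation`, `codes` (list of character
#'   prefixes), `abbr`.
#' @export
read_designation_map <- function(path, kind = c("atc", "icd")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("designation map not found: %s", path))
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          quote = "", comment.char = "#",
                          fileEncoding = "UTF-8")
  stopifnot(all(c("designation", "codes") %in% names(df)))
  codes <- purrr::map(df$codes, function(cs) {
    trimws(strsplit(cs, "|", fixed = TRUE)[[1L]])
  })
  pat <- if (kind == "atc") atc_pattern() else
    "^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$"
  bad <- which(!vapply(codes, function(cs) {
    length(cs) >= 1L && all(grepl(pat, cs))
  }, logical(1)))
  if (length(bad)) {
    abort(sprintf("invalid %s code(s) at line(s) %s", toupper(kind),
                  paste(bad + 1L, collapse = ", ")))
  }
  tibble(
    designation = df$designation,
    codes = codes,
    abbr = if (is.null(df$abbr)) NA_character_ else df$abbr
  )
}

#' Bundled designation maps
#'
#' The drug-group-to-ATC and diagnosis-to-ICD-10 maps used by the
#' replication study configurations.
#'
#' @return Designation tibble, see [read_designation_map()].
#' @export
default_atc_designations <- function() {
  read_designation_map(
    system.file("extdata", "atc_designations.tsv", package = "medtrawl"),
    kind = "atc"
  )
}

#' @rdname default_atc_designations
#' @export
default_icd_designations <- function() {
  read_designation_map(
    system.file("extdata", "icd_designations.tsv", package = "medtrawl"),
    kind = "icd"
  )
}
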