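#' Configuration for the synthetic discharge-letter generator
#'
#' The generator emulates German-style discharge letters: a diagnoses
#' section with ICD-coded phrases and a medication section of comma- or
#' newline-separated instructions `<name> [<strength><unit>] <d1-d2-d3>`.
#' Defaults encode the corpus statistics of routine discharge letters: a
#' strength is present for 90% of instructions, a dosing pattern for 92%,
#' 5% of mentioned drugs are discontinued, 18% of letters also describe
#' the (historical) medication at admission, and daily-unit totals follow
#' the observed distribution dominated by one unit per day (57.4%) and
#' two units (31.0%).  Misspelling and abbreviation rates default to 0
#' (clean text) and are turned up explicitly to study error tolerance.
#'
#' @param seed Integer seed; the generator is deterministic given it.
#' @param n_docs Number of documents (hospital cases).
#' @param drugs_per_doc Length-2 integer range of drugs per letter.
#' @param p_strength,p_instruction,p_discontinued,p_misspell,p_abbreviation
#'   Per-instruction probabilities.
#' @param daily_units_dist Named probability vector over daily-unit
#'   totals; must sum to 1.
#' @param p_admission_section Probability that a letter also carries an
#'   admission-medication section (treated as historical).
#' @param icd_rates Named vector: ICD-10 code to inclusion probability.
#' @param period_start,period_end Discharge-date range (half-open).
#' @param periods Optional tibble `label`, `start`, `end`; documents are
#'   spread evenly over the periods.
#' @param group_prevalence Optional named vector: ATC prefix to the exact
#'   proportion of cases (per period) that carry a drug of that group.
#' @return A validated list of class `medex_gen_config`.
#' @export
gen_config <- function(seed = 1L,
                       n_docs = 100L,
                       drugs_per_doc = c(3L, 8L),
                       p_strength = 0.90,
                       p_instruction = 0.92,
                       p_discontinued = 0.05,
                       p_misspell = 0,
                       p_abbreviation = 0,
                       daily_units_dist = c(
                         "0.25" = 0.001, "0.5" = 0.100, "1" = 0.574,
                         "1.5" = 0.008, "2" = 0.310, "3" = 0.006,
                         "4" = 0.001
                       ),
                       p_admission_section = 0.18,
                       icd_rates = c(I10 = 0.45, I48 = 0.30, E11 = 0.20,
                                     N18 = 0.15, I50 = 0.10, I05 = 0.03),
                       period_start = "2005-01-01",
                       period_end = "2019-01-01",
                       periods = NULL,
                       group_prevalence = NULL) {
  probs <- c(p_strength, p_instruction, p_discontinued, p_misspell,
             p_abbreviation, p_admission_section)
  stopifnot(all(probs >= 0 & probs <= 1))
  if (abs(sum(daily_units_dist) - 1) > 1e-9) {
    abort("daily_units_dist must sum to 1")
  }
  stopifnot(length(drugs_per_doc) == 2L,
            drugs_per_doc[1] >= 1L,
            drugs_per_doc[1] <= drugs_per_doc[2])
  if (!is.null(periods)) {
    stopifnot(all(c("label", "start", "end") %in% names(periods)))
  }
  if (!is.null(group_prevalence)) {
    stopifnot(!is.null(names(group_prevalence)),
              all(group_prevalence >= 0 & group_prevalence <= 1))
  }
  structure(
    list(
      seed = as.integer(seed), n_docs = as.integer(n_docs),
      drugs_per_doc = as.integer(drugs_per_doc),
      p_strength = p_strength, p_instruction = p_instruction,
      p_discontinued = p_discontinued, p_misspell = p_misspell,
      p_abbreviation = p_abbreviation,
      daily_units_dist = daily_units_dist,
      p_admission_section = p_admission_section,
      icd_rates = icd_rates,
      period_start = as.Date(period_start),
      period_end = as.Date(period_end),
      periods = periods, group_prevalence = group_prevalence
    ),
    class = "medex_gen_config"
  )
}

diagnosis_phrase <- function(code) {
  map <- c(
    I10 = "Essentielle Hypertonie", I48 = "Vorhofflimmern",
    E11 = "Diabetes mellitus Typ 2", N18 = "Chronische Nierenkrankheit",
    I50 = "Herzinsuffizienz", I05 = "Rheumatische Klappenkrankheit",
    I21 = "Akuter Myokardinfarkt", I63 = "Hirninfarkt"
  )
  base <- ifelse(is.na(map[code]), "Nebendiagnose", map[code])
  paste0(unname(base), " (", code, ")")
}

#' Introduce a single spelling error into a drug name
#'
#' Applies one edit — substitution, insertion, deletion or adjacent
#' transposition — at a random position, so the result is at
#' Damerau-Levenshtein distance exactly 1 from the input.
#'
#' @param name Product name (at least 4 characters).
#' @param mode One of `"substitution"`, `"insertion"`, `"deletion"`,
#'   `"transposition"`; `NULL` picks one at random (transposition only
#'   where an adjacent unequal pair exists).
#' @return The misspelled name.
#' @export
corrupt_name <- function(name, mode = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (nchar(name) < 4L) {
    abort(sprintf("name too short to corrupt: '%s'", name))
  }
  ch <- strsplit(name, "")[[1L]]
  n <- length(ch)
  trans_pos <- which(ch[-n] != ch[-1])
  modes <- c("substitution", "insertion", "deletion",
             if (length(trans_pos)) "transposition")
  if (is.null(mode)) mode <- sample(modes, 1L)
  stopifnot(mode %in% c("substitution", "insertion", "deletion",
                        "transposition"))
  switch(mode,
    substitution = {
      p <- sample.int(n, 1L)
      ch[p] <- sample(setdiff(letters, tolower(ch[p])), 1L)
      paste(ch, collapse = "")
    },
    insertion = {
      p <- sample.int(n + 1L, 1L)
      paste(c(ch[seq_len(p - 1L)], sample(letters, 1L),
              ch[seq_len(n)[seq_len(n) >= p]]), collapse = "")
    },
    deletion = {
      p <- sample.int(n, 1L)
      paste(ch[-p], collapse = "")
    },
    transposition = {
      if (!length(trans_pos)) abort("no adjacent unequal pair to swap")
      p <- if (length(trans_pos) == 1L) trans_pos else
        sample(trans_pos, 1L)
      tmp <- ch[p]
      ch[p] <- ch[p + 1L]
      ch[p + 1L] <- tmp
      paste(ch, collapse = "")
    }
  )
}

#' Generate a synthetic discharge-letter corpus with gold annotations
#'
#' Deterministic given the configuration seed.  Returns the documents and
#' a gold table recording, for every generated instruction, the canonical
#' drug, ATC code, the (pre-corruption) truth for strength, dosing
#' pattern and daily dose, context (discontinued, historical), whether
#' the surface was misspelled or abbreviated, and the character span of
#' the drug name in the document text.
#'
#' @param cfg A [gen_config()].
#' @param db Drug lexicon from [read_drug_db()]; entries need at least a
#'   processed name.
#' @return A list with elements `docs` (corpus tibble as in
#'   [read_corpus_jsonl()]), `gold` (annotation tibble) and `config`.
#' @export
generate_corpus <- function(cfg = gen_config(), db = default_drug_db()) {
  stopifnot(inherits(cfg, "medex_gen_config"))
  if (nrow(db) == 0L) abort("empty drug lexicon")
  withr::local_seed(cfg$seed)
  catalog <- default_pattern_catalog()

  periods <- cfg$periods %||% tibble(
    label = "all", start = cfg$period_start, end = cfg$period_end
  )
  np <- nrow(periods)
  doc_period <- rep(seq_len(np), length.out = cfg$n_docs)

  # exact per-period assignment of prevalence-controlled ATC groups
  group_assign <- list()
  if (!is.null(cfg$group_prevalence)) {
    for (g in names(cfg$group_prevalence)) {
      flag <- logical(cfg$n_docs)
      for (p in seq_len(np)) {
        ids <- which(doc_period == p)
        k <- round(cfg$group_prevalence[[g]] * length(ids))
        if (k > 0L) flag[ids[sample.int(length(ids), k)]] <- TRUE
      }
      group_assign[[g]] <- flag
    }
  }
  ctl_prefixes <- names(group_assign)
  in_group <- function(prefix) startsWith(db$atc_code, prefix)

  docs <- vector("list", cfg$n_docs)
  gold <- vector("list", cfg$n_docs)
  for (d in seq_len(cfg$n_docs)) {
    pd <- periods[doc_period[d], ]
    span_days <- as.integer(as.Date(pd$end) - as.Date(pd$start))
    discharge <- as.Date(pd$start) + sample.int(max(span_days, 1L), 1L) - 1L
    admission <- discharge - sample.int(14L, 1L)
    age <- sample(30:95, 1L)
    sex <- sample(c("m", "f"), 1L)
    icds <- names(cfg$icd_rates)[
      runif(length(cfg$icd_rates)) < cfg$icd_rates
    ]

    forced <- integer(0)
    for (g in ctl_prefixes) {
      if (group_assign[[g]][d]) {
        forced <- c(forced, sample_one(which(in_group(g))))
      }
    }
    allowed <- seq_len(nrow(db))
    for (g in ctl_prefixes) {
      if (!group_assign[[g]][d]) allowed <- setdiff(allowed,
                                                    which(in_group(g)))
    }
    allowed <- setdiff(allowed, forced)
    n_drugs <- sample_one(cfg$drugs_per_doc[1]:cfg$drugs_per_doc[2])
    n_extra <- max(0L, n_drugs - length(forced))
    picks <- c(forced,
               allowed[sample.int(length(allowed),
                                  min(n_extra, length(allowed)))])

    med <- make_instructions(db[picks, , drop = FALSE], cfg, catalog)

    # admission-medication section: historical context
    adm <- NULL
    if (runif(1) < cfg$p_admission_section && length(allowed) > 2L) {
      adm_pool <- setdiff(allowed, picks)
      adm_picks <- adm_pool[sample.int(
        length(adm_pool), min(sample_one(1:3), length(adm_pool))
      )]
      if (length(adm_picks)) {
        adm <- make_instructions(db[adm_picks, , drop = FALSE], cfg,
                                 catalog)
      }
    }

    built <- build_letter(icds, med, adm)
    doc_id <- sprintf("doc%05d", d)
    docs[[d]] <- tibble(
      doc_id = doc_id,
      patient_id = sprintf("pat%05d", d),
      case_id = sprintf("case%05d", d),
      admission_date = admission, discharge_date = discharge,
      age_years = age, sex = sex,
      icd_codes = list(icds), text = built$text
    )
    g <- built$gold
    if (nrow(g)) g$doc_id <- doc_id
    gold[[d]] <- g
  }
  docs <- bind_rows(docs)
  gold <- bind_rows(gold)
  if (nrow(gold)) {
    gold <- gold[, c("doc_id", setdiff(names(gold), "doc_id"))]
  }
  list(docs = docs, gold = gold, config = cfg)
}

# draw surface text + gold truth for a set of lexicon rows
make_instructions <- function(entries, cfg, catalog) {
  n <- nrow(entries)
  o_term <- o_surface <- o_unit <- o_instruction <- character(n)
  o_strength <- o_du <- o_dose <- rep(NA_real_, n)
  o_disc <- o_miss <- o_abbr <- logical(n)
  o_pattern <- vector("list", n)
  for (i in seq_len(n)) {
    name_tokens <- entries$processed[[i]]
    term <- paste(name_tokens, collapse = " ")
    surface_name <- term
    misspelled <- FALSE
    abbreviated <- FALSE
    if (cfg$p_misspell > 0 && nchar(name_tokens[1]) >= 5L &&
        runif(1) < cfg$p_misspell) {
      parts <- strsplit(surface_name, " ", fixed = TRUE)[[1L]]
      parts[1] <- corrupt_name(parts[1])
      surface_name <- paste(parts, collapse = " ")
      misspelled <- TRUE
    } else if (cfg$p_abbreviation > 0 && nchar(name_tokens[1]) >= 6L &&
               runif(1) < cfg$p_abbreviation) {
      keep <- sample(4:(nchar(name_tokens[1]) - 1L), 1L)
      surface_name <- substr(name_tokens[1], 1L, keep)
      abbreviated <- TRUE
    }

    strengths <- entries$strengths[[i]]
    if (length(strengths) == 0L) strengths <- c(5, 10, 20, 25, 50, 100)
    has_strength <- runif(1) < cfg$p_strength
    strength <- if (has_strength) sample_one(strengths) else NA_real_
    unit <- entries$unit[i]
    has_pattern <- runif(1) < cfg$p_instruction
    if (has_pattern) {
      u <- as.numeric(sample(names(cfg$daily_units_dist), 1L,
                             prob = cfg$daily_units_dist))
      pats <- catalog[[format(u)]]
      pattern <- pats[[sample.int(length(pats), 1L)]]
    } else {
      pattern <- NULL
    }
    discontinued <- runif(1) < cfg$p_discontinued

    txt <- surface_name
    if (has_strength) {
      sep <- sample(c("", " "), 1L)
      txt <- paste0(txt, " ", format_num_token(strength), sep, unit)
    }
    if (has_pattern) {
      txt <- paste0(txt, " ",
                    paste(format_num_token(pattern), collapse = "-"))
    }
    if (discontinued) {
      txt <- paste0(txt, " ", sample(c("pausiert", "abgesetzt"), 1L))
    }
    du <- if (has_pattern) sum(pattern) else NA_real_
    o_term[i] <- term
    o_surface[i] <- surface_name
    o_strength[i] <- strength
    o_unit[i] <- if (has_strength) unit else NA_character_
    o_pattern[i] <- list(pattern)  # keeps NULL as an element
    o_du[i] <- du
    o_dose[i] <- if (has_pattern && has_strength) strength * du else
      NA_real_
    o_disc[i] <- discontinued
    o_miss[i] <- misspelled
    o_abbr[i] <- abbreviated
    o_instruction[i] <- txt
  }
  tibble(
    canonical = entries$product_name, atc_code = entries$atc_code,
    term = o_term, surface_name = o_surface,
    strength = o_strength, unit = o_unit, pattern = o_pattern,
    daily_units = o_du, daily_dose = o_dose,
    discontinued = o_disc, misspelled = o_miss, abbreviated = o_abbr,
    instruction = o_instruction
  )
}

# assemble the letter text, tracking the char span of each drug name
build_letter <- function(icds, med, adm) {
  pieces <- character(0)
  cursor <- 0L
  push <- function(s) {
    pieces[length(pieces) + 1L] <<- s
    cursor <<- cursor + nchar(s, type = "chars")
  }
  push("Diagnosen:\n")
  for (code in icds) push(paste0(diagnosis_phrase(code), "\n"))
  if (length(icds) == 0L) push("Keine kodierten Diagnosen\n")
  push("\n")

  gold <- list()
  emit_section <- function(header, instr, historical) {
    push(paste0(header, "\n"))
    starts <- integer(nrow(instr))
    for (i in seq_len(nrow(instr))) {
      starts[i] <- cursor
      push(instr$instruction[i])
      if (i < nrow(instr)) {
        push(sample(c(", ", "\n"), 1L))
      }
    }
    push("\n")
    instr$historical <- historical
    instr$start <- starts
    instr$end <- starts + nchar(instr$surface_name, type = "chars")
    gold[[length(gold) + 1L]] <<- instr
  }
  if (!is.null(med) && nrow(med)) {
    emit_section("Medikation bei Entlassung:", med, historical = FALSE)
  }
  if (!is.null(adm) && nrow(adm)) {
    push("\n")
    emit_section("Medikation bei Aufnahme:", adm, historical = TRUE)
  }
  g <- bind_rows(gold)
  if (nrow(g)) g$instruction <- NULL
  list(text = paste(pieces, collapse = ""), gold = g)
}
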