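---
title: "Ad hoc medication and daily-dose extraction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ad hoc medication and daily-dose extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medtrawl)
```

## The problem

Hospital discharge letters carry the authoritative record of what a
patient is taking at discharge, but they carry it as free text: a
medication section of short, formulaic instructions such as

```
Medikation bei Entlassung:
Delix 5mg 1-0-0, Esidrix 12,5 mg 1-0-0
Marcumar pausiert
```

Drug-utilization research wants two things from this text: a Boolean
answer per case ("is a drug of ATC group C07 currently taken?") and a
numeric one (the daily dose).  medtrawl implements the query-time
("ad hoc") approach: the text is tokenized and indexed once, and every
study question is an index query — there is no study-specific
annotation pass.  All user-facing functions take and return tibbles so
that pipelines compose with the usual tidyverse verbs.

## Lexical analysis

`split_sections()` cuts a letter at recognised header lines
(configurable bilingual lexicon; admission-medication headers are marked
historical).  `segment_instructions()` then splits medication sections
at newlines, semicolons and commas into one sentence per drug
instruction — a comma flanked by digits, as in `12,5`, is a decimal
comma and never a separator.  One instruction per sentence is what makes
proximity queries safe: they cannot leak dosage numbers across drugs.

`tokenize()` decomposes instructions without stemming (drug-name endings
are meaningful): alphanumeric boundaries split (`10mg` → `10`, `mg`),
hyphens and dashes separate (`1-0-0`, `Mono-Mack`), slash fractions and
decimal numbers stay whole.  Two details are choices this package makes
where reasonable tokenizers differ:

* a slash number is one `fraction` token only when the numerator is
  smaller than the denominator.  Dosing fractions (`1/2`) are proper;
  clinical ratios such as blood pressure (`135/80`) are not, and
  splitting them lets numeric-concept extraction return 135 for
  `RR 135/80 mmHg`.
* the multiplication notation (`Esidrix 1x1`) is tokenized literally
  (`1`, `x`, `1`) and *not* interpreted as a dosing pattern; systems of
  this design count it as an extraction failure mode, and we keep that
  behaviour rather than silently guessing.

Character offsets are 0-based and half-open throughout, and token spans
reconstruct the input exactly (a property test enforces this), so every
downstream annotation can be traced back to the letter.

## Context: negation, history, discontinuation

A mention is not an intake.  `annotate_context()` is a NegEx/ConText
style scope marker: trigger phrases (e.g. "kein", "pausiert", "bei
Aufnahme", "Mutter") set a category flag — negated, discontinued,
historical, other-subject — on tokens from the trigger to the sentence
boundary in the trigger's direction, stopping at scope terminators
("aber", "but").  Whole sections opened by admission-medication headers
are historical.  `filter_active()` keeps only unflagged instructions.

The shipped trigger lexicon is deliberately small and is configuration,
not code: local documentation style varies, and the TSV schema
(`phrase, category, direction, terminators`) accepts site-specific
extensions.  Scope-to-sentence-boundary is the standard convention and
is what makes the monotonicity property hold: adding a trigger can only
shrink the set of active sentences.

## The index and the query algebra

`build_index()` holds a positional postings table (token → document,
sentence, position) plus a sentence store with context flags — an
in-memory stand-in for a search server, sized for corpora that fit in
R's memory.  Queries are trees built from `query_term()`,
`query_fuzzy()`, `query_phrase()`, `query_near()`, Boolean nodes and
`query_active()`; `parse_query()` accepts a compact text DSL.

Error-tolerant matching uses the Damerau–Levenshtein distance in the
optimal-string-alignment variant (insertion, deletion, substitution,
adjacent transposition; a transposed pair is not re-edited).  Manually
entered drug names are typically one such edit from the lexicon form
(`Ibohexal`, `Rampiril`).  The default threshold is length-dependent —
exact under 5 characters, 1 edit for 5–9, 2 edits from 10 — because
fuzzy matching of short common words is the dominant false-positive mode
(`diabetes` ≈ `diabetex`); the unit tests keep this failure mode visible
instead of hiding it.

Proximity queries require their tokens, as a multiset, inside a window
of `length(tokens) + slop` positions of one sentence (default slop 1
tolerates an interleaved unit token).  Two numeric query tokens must
additionally occur in their given order (`ordered_numbers = TRUE`):
word order in instructions is free (`mg` may wander), but the dosing
pattern `1-0-0` is a schedule, and treating its numbers as an unordered
bag would equate different schedules.  The permuted snippet
`Delix 5-mg 0 1 0` therefore does not match a `Delix 5 1 0 0` query,
although its token multiset is compatible — matching it would only be
correct under the reading that daily *totals* are equal, which is what
dose-query expansion (below) already provides explicitly.  The flag is
per query for users who want bag semantics.

Both the query engine and the edit distance are verified against
independent brute-force oracles (exhaustive sentence scans,
full-matrix dynamic programming) on randomized corpora in the test
suite.

## Doses

A dose instruction has two components after the drug name: a strength
(number directly followed by a unit: mg, µg, g, ml, IE) and a dosing
pattern of 3–4 schedule numbers (morning–noon–evening[–night]).  The
daily dose is `strength × sum(pattern)`.

`parse_dose_instruction()` takes the first strength pair starting within
`max_gap` tokens of the drug name (default 2) and the first run of 3–4
schedule numbers within `pattern_gap` tokens after it (default 4, so a
short parenthetical like `(bei Bedarf)` is skipped; both defaults trade
recall against picking up numbers that belong to a neighbouring
phrase).  Schedule slots are restricted to the plausible per-slot
alphabet {0, 1/4, 1/3, 1/2, 3/4, 1, 1.5, 2, 3, 4}: a strength written in
pattern position (`150-0-150 mg`) or a bare strength (`Mono-Mack 20`) is
then never misread as a schedule — those notations yield an absent
component, the same behaviour such systems report as an error class.
Absence is a value, not an error: roughly one instruction in ten has no
strength and one in twelve no pattern, and the distribution machinery
accounts for it.

`expand_dose_query()` goes the other way: given a drug, strength and
daily-unit total it builds an OR of proximity queries, one per catalog
pattern with that sum.  The pattern catalog is configuration (default:
all 3-slot patterns over {0, 1/4, 1/2, 1, 2} for the totals seen in
practice, 0.25–4); the published worked example prints only the first
disjuncts of such an expansion.  A cross-validation test generates a
corpus and checks that the two pathways — query expansion and sig
parsing — agree on every hit.

`aggregate_dose_distribution()` tabulates (daily units × strength) over
non-discontinued instructions, and `average_daily_dose()` is the
proportion-weighted mean `Σ p·u·s / Σ p`, reported in the unit of the
distribution (µg→mg conversion is deliberately not automatic).  When
recomputing a published average from a table of rounded percentages,
the result can differ from the printed average by up to about 0.1 in
the last printed digit — that is rounding of the cells, not a model
discrepancy.

## Cohorts and trends

`cohort_filter()`/`apply_cohort_filter()` implement the usual
replication criteria: ICD-10 include/exclude prefixes, a half-open
discharge-date range, inclusive age bounds, optional sex.  Counting is
case-level by default (a `per_patient` flag deduplicates), because
admission-level prevalences are what the trend literature reports; age
adjustment is out of scope.  `drug_prevalence_trend()` answers the
Boolean question per period × ATC group through the index, counting a
case once however many group drugs it mentions.  Designation maps
(drug-group → ATC, diagnosis → ICD) and a worked study configuration
ship as TSV/YAML under `inst/extdata/`.

## The synthetic generator, and what passing tests mean

Clinical texts cannot leave their network, so the package ships
`generate_corpus()`: a seeded generator of German-style letters with a
diagnoses section, a medication section of instructions
`<name> [<strength><unit>] <d1-d2-d3>`, optional admission-medication
sections, and a gold record per instruction.  The defaults are the
study conditions, fixed once: 90% of instructions carry a strength, 92%
a pattern, 5% are discontinued, 18% of letters carry an admission
section, and daily-unit totals follow the observed distribution (1 unit
57.4%, 2 units 31.0%, 1/2 unit 10.0%, the rest rare).  Misspelling and
abbreviation rates default to zero and are switched on explicitly:
`corrupt_name()` applies exactly one edit (so fuzzy matching at
distance 1 is exercised honestly), and abbreviation truncates to a
prefix of at least 4 characters, which is *expected* to cause misses
unless the abbreviation is a lexicon alternative name — mirroring the
dominant real error class rather than hiding it.

The generator draws names from the shipped lexicon, a ~50-entry
synthetic stand-in for a licensed drug database (same TSV schema, so a
full export drops in).  What the generator does **not** emulate: prose
narrative around sections, out-of-lexicon drugs, free-text frequency
instructions ("alle 2 Stunden"), tapering schedules, PRN logic, and
OCR-level noise.  Perfect scores on clean synthetic text therefore
demonstrate that the machinery is lossless under its own assumptions —
closed vocabulary, template grammar — not that real-world F1 is 1.0;
the realistic error modes that remain on real text are exactly the
documented ones (abbreviations, out-of-lexicon names, unusual
notations).

## Numerical and degenerate-input choices

* Case folding is plain lowercasing; umlauts and ß are preserved (no
  transliteration — the fuzzy distance absorbs residual variation).
* Numeric token comparison in the engine is by value ("1/2" matches
  "0,5") with an absolute tolerance of 1e-9; token `norm` stays the
  case-folded surface.
* Overlapping drug-name matches in one sentence resolve longest-first.
* Empty inputs are values: empty text yields one `other` section; a
  drug name that normalizes to nothing falls back to its first token;
  an empty dose distribution is an error (there is no average to
  report); a period with no cases reports 0% with an `undefined` flag.
* Dates are half-open `[start, end)` on the discharge date; ages are
  inclusive.

## Problem sizes in the shipped tests

The test suite generates corpora of 1,000 documents (≈5,300
instructions) for the end-to-end recovery and fuzzy-recall checks, 200
randomized mini-corpora for the engine-vs-oracle equivalence, 10,000
random string pairs for the distance oracle, and 250 documents across 5
periods for trend recovery — sizes chosen so the whole suite runs in a
few minutes on one core while keeping sampling error well inside the
asserted bounds.

## Known limitations

* The index is in-memory and unranked; it is a method testbed, not a
  search server.
* Strengths are only recognised with an explicit unit token; bare
  numbers after names are deliberately ignored.
* The dose-slot alphabet excludes totals above 4 units and uncommon
  splits unless the catalog is extended.
* Context detection is trigger-based with sentence-bounded scopes;
  there is no temporal normalization and no hedging/uncertainty
  detection.
* German templates dominate the generator; English surface forms exist
  but are minimal.
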