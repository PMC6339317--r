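Package: medtrawl
Title: Ad Hoc Medication and Daily-Dose Extraction from Discharge Letters
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Query-time (ad hoc) information extraction of medication use
    and daily dosage from the free text of hospital discharge letters.
    Provides a section splitter and instruction tokenizer for German-style
    medication sections, ConText-style detection of negated, historical,
    other-subject and discontinued mentions, a positional in-memory index
    with error-tolerant (Damerau-Levenshtein), phrase and proximity
    queries, strength and dosing-pattern (sig) parsing with daily-dose
    computation and aggregation, ATC-grouped drug-utilization trend tables
    over ICD-10-filtered cohorts, and a seeded synthetic discharge-letter
    generator with gold annotations for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
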