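# medtrawl

Ad hoc (query-time) extraction of **medication use and daily dosage**
from the free text of hospital discharge letters, for drug-utilization
and study-replication research on clinical data warehouses.

Discharge letters list prescriptions as short formulaic instructions —
`<name> [<strength><unit>] <morning-noon-evening[-night]>`, e.g.
`Delix 5mg 1-0-0` — inside a medication section.  medtrawl turns a
corpus of such letters into a queryable positional index and answers
the two questions drug-utilization studies ask:

* **Boolean**: does a case currently take a drug of ATC group *g*?
  (cohort prevalences, trend tables)
* **Numeric**: at what daily dose?
  (daily dose = strength × Σ pattern, e.g. `Pradaxa 110 mg 1-0-1` →
  2 × 110 mg = 220 mg)

The pipeline is: section splitting → instruction segmentation →
tokenization (no stemming) → ConText-style filtering of negated /
historical / other-subject / **discontinued** mentions → positional
index with term, phrase, **error-tolerant** (Damerau–Levenshtein, OSA
variant) and **proximity** queries → sig parsing and dose aggregation →
ICD-filtered cohort trend tables.  A seeded synthetic discharge-letter
generator with gold annotations makes the whole chain testable without
protected clinical text.

## Worked example

```r
library(medtrawl)

letter <- paste0(
  "Diagnosen:\nVorhofflimmern (I48)\n\n",
  "Medikation bei Entlassung:\n",
  "Delix 5mg 1-0-0, Esidrix 12,5 mg 1-0-0\n",
  "Pradaxa 110 mg 1-0-1\n",
  "Marcumar pausiert\n"
)
docs  <- tibble::tibble(doc_id = "case-1", text = letter)
built <- build_corpus_index(docs)

extract_medications(built$index, default_drug_db())
#>   canonical atc_code strength unit daily_units daily_dose
#> 1     Delix  C09AA05      5.0   mg           1        5.0
#> 2   Esidrix  C03AA03     12.5   mg           1       12.5
#> 3   Pradaxa  B01AE07    110.0   mg           2      220.0
```

Three instructions are recognised, normalized to their ATC codes, and
their daily doses computed (`12,5` is a decimal comma, `1-0-1` sums to
2 units).  `Marcumar pausiert` is absent: the backward discontinuation
trigger flags it and `extract_medications()` drops non-current
medication by default.

Queries work directly, including misspelled ones and context flags:

```r
execute(parse_query("~1Pradexa"), built$index)$snippet
#> [1] "Pradaxa 110 mg 1-0-1"
nrow(execute(parse_query("Marcumar -discontinued"), built$index))
#> [1] 0
```

Dose distributions aggregate per drug and average by proportion weight:

```r
dist <- aggregate_dose_distribution(
  tibble::tibble(daily_units = c(1, 2, 2), strength = c(110, 110, 150),
                 unit = "mg"),
  drug = "Pradaxa")
average_daily_dose(dist)
#> [1] 210
```

For cohort trends, `cohort_filter()` + `drug_prevalence_trend()` build
period × ATC-group prevalence tables; `autoplot()` methods chart dose
distributions and trends, and `generate_corpus(gen_config(seed = 1))`
creates a gold-annotated synthetic corpus to validate a configuration
end to end.  See the methods vignette
(`vignettes/medication-extraction.Rmd`) for the model, parameters and
design decisions.

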