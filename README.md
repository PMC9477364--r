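# chronoage

Tools for the **ChronometricAge extension to Darwin Core**: publishing,
validating and querying the age of archaeological and paleontological
specimens attached to biodiversity occurrence records.

## The problem

Darwin Core's `eventDate` records when a specimen was *collected*, not how
old the specimen *is*. As a result, chronometric ages — radiocarbon assays,
Ar/Ar and U–Pb dates, ceramic seriation, historical-document syntheses —
have historically been scattered through free-text fields
(`lithostratigraphicTerms`, `identificationRemarks`, `dynamicProperties`),
where they are nearly impossible to find or query. The ratified
ChronometricAge extension gives this information a controlled vocabulary and
a star-schema home: many extension rows per occurrence, every field
optional, with explicit reporting of the material dated, the assay, the age
bounds, their reference systems and their uncertainty.

`chronoage` implements the extension end to end:

* **Vocabulary** — the term-version registry with a bundled snapshot of the
  ratified vocabulary (`load_term_registry()`, `resolve_term()`).
* **Chronology** — normalization of heterogeneous age reference systems
  (BP, BCE/CE, ka, Ma, Ga) onto a canonical axis of calendar years before
  1950 CE, with interval queries. For ages `a` expressed in a convertible
  reference system:

  - before-present kinds: `t = a · s`, with scale `s ∈ {1, 10³, 10⁶, 10⁹}`;
  - calendar labels via astronomical year numbering `y*` (no year zero:
    `y* = y` for y CE, `y* = 1 − y` for y BCE): `t = 1950 − y*`.

  Uncalibrated radiocarbon ages (`uncal BP`, `14C yr BP`) are *never*
  placed on this axis — calibration is curve-dependent and out of scope —
  so they can't silently corrupt temporal queries.
* **Record model + validation** — `validate_record()` /
  `validate_dataset()` apply a closed set of 12 quality flags
  (ERROR/WARNING/INFO) that make "no required fields" safe to consume.
* **Darwin Core Archive I/O** — meta.xml-driven reading (zip or directory)
  and deterministic writing with many-to-one extension rows
  (`read_archive()`, `write_archive()`).
* **dynamicProperties JSON** — embed/extract ages as
  `{"chronometricAge":[...]}` inside `dwc:dynamicProperties` so they stay
  visible in flat occurrence downloads, plus a drift check between the two
  published copies.
* **Scanner** — the legacy-field audit: per-field unique-value and
  chronometry-match counts over targeted Darwin Core fields, with
  token-mode matching on maximal alphabetic runs ("Ma" matches
  "16 Ma tuff", never "Mammal").
* **Fixtures** — deterministic exemplar presets and a synthetic legacy
  corpus with planted matches and exact ground truth.

## Worked example

```r
library(chronoage)

# A two-assay age bracket: one occurrence, two extension records
hr <- make_preset("hawk_rim")
hr$chronometric_ages[, c("chronometricAgeID", "chronometricAgeProtocol",
                         "earliestChronometricAge", "latestChronometricAge")]
#> # A tibble: 2 × 4
#>   chronometricAgeID chronometricAgeProtocol           earliestChronometricAge
#>   <chr>             <chr>                             <chr>
#> 1 HR-CA-1           40Ar/39Ar dating of volcanic tuff "16.16"
#> 2 HR-CA-2           U-Pb dating of zircon             ""
#> # ℹ 1 more variable: latestChronometricAge <chr>

# Normalize onto the canonical axis (years before 1950, larger = older)
interval_from_record(hr$chronometric_ages[1, ])
#> <age interval: 1.616e+07 .. 1.616e+07 yr BP (one-sided)>

# Does a record's age window overlap a query window?
nm <- make_preset("north_midden")
iv <- interval_from_record(nm$chronometric_ages)   # [3360, 3165] cal BP
overlaps(iv, age_interval(3500, 3300))
#> [1] TRUE

# Quality flags: swap the bounds and the dataset validator objects
bad <- apply_corruption(nm, "INVERTED_AGE_BOUNDS")
validate_dataset(bad$occurrence$id, bad$chronometric_ages)$code
#> [1] "INVERTED_AGE_BOUNDS"

# Audit a messy legacy corpus for hidden chronometry
corpus <- make_legacy_corpus(corpus_spec(n_records = 10000))
scan_summary(scan_occurrences(corpus$records))
#> # A tibble: 5 × 3
#>   field                   uniqueValueCount matchedValueCount
#>   <chr>                              <int>             <int>
#> 1 eventDate                             56                 0
#> 2 verbatimEventDate                     55                 0
#> 3 dynamicProperties                    198               144
#> 4 identificationRemarks                 88                32
#> 5 lithostratigraphicTerms              426               370
```

`matchedValueCount` counts *distinct* field values containing at least one
chronometry search term (the defaults: BCE, BC, CE, AD, BP, Ky, Kya, My,
Ma, Mya as case-sensitive tokens, "dating method" as a case-insensitive
phrase). Here the scanner recovers exactly the 144/32/370 planted values
and nothing else — decoys like "Mammal" and "Madagascar" never match.

## Command line

A thin wrapper script is installed with the package
(`system.file("scripts", "chronoage.R", package = "chronoage")`):

```sh
Rscript chronoage.R terms list
Rscript chronoage.R validate my-archive/          # exit 0 iff no ERROR issue
Rscript chronoage.R convert my-archive/ --report intervals.csv
Rscript chronoage.R fixtures --preset hawk_rim --out demo/
```

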