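---
title: "Chronometric ages on Darwin Core occurrences: model, validation and audit methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronometric ages on Darwin Core occurrences: model, validation and audit methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoage)
```

## The data model

A chronometric age is an evidence-supported approximation of a specimen's
temporal position — how old the thing is, as opposed to `eventDate`, which
by universal provider practice records when it was collected. The
ChronometricAge extension expresses this as extension rows in a Darwin Core
Archive star schema: one core occurrence file, an extension file whose rows
each describe one age determination, linked by a `coreid`. Three design
facts drive everything in this package:

1. **Nothing is mandatory.** Every property term is individually optional,
   so consumers need conditional validation, not schema validation.
2. **Many rows per specimen.** One occurrence may carry several age
   records — multiple assays, or two one-sided bounds that jointly bracket
   an age range — so row multiplicity is first-class, never an error.
3. **Both relative and absolute evidence.** Assay outputs (an AMS
   radiocarbon measurement), syntheses (historical documents plus ceramic
   typology) and brackets (tephra above and below) must all be expressible.

Records are stored as plain text tibbles with the 18 property-term columns
plus `coreReference`, exactly as they travel in an archive; numeric fields
are parsed at the point of use. The class term `chronometricAge` names the
record itself and is kept in the vocabulary registry alongside the
properties.

## The canonical timeline

Age bounds arrive against heterogeneous reference systems. To make
intervals comparable the package maps every *convertible* system onto one
axis: **real-valued calendar years before 1950 CE, larger = older**. BP is
the lingua franca of chronometric reporting, and this orientation makes
"earliest = larger" uniform across the package.

| kind | example labels | mapping to canonical years `t` |
|------|----------------|-------------------------------|
| BP   | `BP`, `cal BP`, `years BP` | `t = a` |
| KA / MA / GA | `ka`, `Kya`, `Ma`, `Mya`, `Ga` | `t = a · 10³ / 10⁶ / 10⁹` |
| CE   | `CE`, `AD` | `t = 1950 − y` |
| BCE  | `BCE`, `BC` | `t = 1950 − (1 − y)` |

Decisions worth spelling out:

* **No year zero.** Historical-calendar labels go through astronomical
  year numbering (1 BCE ↦ year 0), the convention archaeologists use, so
  1 BCE and 1 CE are adjacent: `canonical(1 BCE) − canonical(1 CE) = 1`.
  The tests check the whole mapping against an independently enumerated
  label sequence rather than re-deriving the same formula.
* **ka/Ma/Ga use the 1950 datum.** The ≤ 50-year offset between "present"
  conventions is orders of magnitude below the precision of such ages;
  this is documented, not configurable.
* **Uncalibrated radiocarbon ages never reach the canonical axis.**
  Calibration is nonlinear and curve-dependent; treating ¹⁴C yr BP as
  calendar years is exactly the silent corruption the extension exists to
  prevent. `uncal BP` / `14C yr BP` labels parse to a recognized but
  non-convertible kind, and conversion attempts raise a typed error.
* **Label parsing is total.** Any unrecognized label yields kind
  `UNKNOWN` (also non-convertible) rather than an exception; the validator
  turns it into a warning. Matching is case-insensitive after trimming
  against a closed synonym list — free-text fuzzy matching would trade
  silent false positives for convenience.

### Intervals

A record's bounds become a closed interval `[older, younger]` on the
canonical axis, each bound converted under *its own* reference system (the
two may legitimately differ, e.g. `2 ka` and `1500 BP`). Two choices here
were genuinely open:

* **One-sided records produce degenerate intervals** (`older == younger`,
  flagged `one_sided`) rather than unbounded ones. This is conservative:
  inventing an unstated bound (0? the age of the Earth?) would make
  overlap queries assert knowledge nobody reported.
* **Overlap is closed-interval**: endpoint contact counts. The use case is
  recall-biased chronological search, where missing a boundary record is
  the worse failure. The implementation (`a.older ≥ b.younger ∧
  b.older ≥ a.younger`) is checked against a brute-force 1-year
  rasterization on randomized instances.

`chronometricAgeUncertaintyInYears` expands an interval symmetrically:
`[older + u, younger − u]`, growing the width by exactly `2u`. The younger
bound may cross the 1950 datum and go negative; no clamping is applied,
and the validator flags post-1950 bounds as a warning only.

## Validation rules and severity policy

Because the standard mandates nothing, hard failures are reserved for
self-contradiction. The rule set is a closed, documented list of 12 codes;
the policy is: **anything that would corrupt a temporal query is ERROR**
(non-numeric bounds, inverted bounds, negative uncertainty, malformed
determination dates, orphaned extension rows); **anything that merely
reduces interpretability is WARNING or INFO** (a bound without a reference
system, an unrecognized reference system, a fully empty record, duplicate
record identifiers, uncalibrated output published without its conversion
protocol). Validation itself never throws on content — a fuzz test feeds
arbitrary junk through every field.

Numeric parsing is deliberately strict about separators: `"3,040"` is
`NON_NUMERIC_AGE`, because thousands-separator tolerance is
locale-dependent and silently corrupts ages by factors of 1000 in the
other locale. Plain decimals, surrounding whitespace and scientific
notation are accepted. `chronometricAgeDeterminedDate` follows Darwin Core
`eventDate` practice: ISO 8601 years, months, days, and `/`-separated
intervals.

The rule suite is verified by *mutation testing*: for each code, a
generating corruption applied to a clean exemplar fixture must add exactly
that code and nothing else. This catches both missed detections and rule
cross-talk.

Cross-field chronology between `uncalibratedChronometricAge` and the
calibrated bounds is deliberately *not* checked — doing it would require a
calibration curve, which is out of scope; only the co-presence INFO rule
fires.

## Archive and JSON dialects

The **reader** is entirely meta.xml-driven: column-to-term mapping follows
the declared zero-based index attributes even when a header row disagrees,
each file's delimiter/quote/encoding dialect is honored, short rows are
padded with empty values under a warning, undecodable bytes raise an error
naming file and line, and extension files of unrecognized row types are
preserved opaquely rather than dropped. Zip archives and unpacked
directories are both accepted.

The **writer** fixes one dialect for reproducibility: UTF-8, tab
delimiters, LF line endings, one header line, values quoted only when they
contain a delimiter, quote or line break; extension rows sorted by
`(coreReference, chronometricAgeID)` so repeated exports diff cleanly;
columns emitted only for terms with at least one non-empty value (an
all-empty column asserts nothing and bloats archives). The writer emits an
unpacked archive directory — zip packaging varies by platform tooling, and
a directory is the lossless common denominator the reader accepts. The
core record's `id` is written verbatim as the coreid.

The **dynamicProperties dialect** exists because aggregator portals hide
extension files: a JSON copy in the occurrence row keeps ages visible in
flat downloads. The envelope is `{"chronometricAge": [ ... ]}` — always an
array, since multiplicity is first-class, though a bare object is accepted
on read. Member keys are term local names in standard order; numeric terms
are emitted as JSON numbers only when the text form survives the number
round-trip byte-exactly, so embedding is lossless by construction. The
reader is tolerant: sibling dynamic properties pass through, unknown keys
inside a member are skipped with an `UNKNOWN_TERM` note, and non-JSON
input yields an empty result plus a note, never an exception. When both
copies of the data exist, `check_embedded_consistency()` reports drift,
matching records by `chronometricAgeID` when available and positionally
otherwise.

## The audit scanner

The scanner reimplements the gap-analysis methodology used to motivate the
extension: aggregate the **distinct** non-empty trimmed values of each
targeted field (`eventDate`, `verbatimEventDate`, `dynamicProperties`,
`identificationRemarks`, `lithostratigraphicTerms`), restricted to
`basisOfRecord = "FossilSpecimen"`, then count values matching a search
term list. Counting unique values rather than record occurrences is the
documented choice: aggregators hold huge blocks of duplicated strings, and
unique-value counts measure vocabulary, not data volume.

Matching rules were an open question, resolved as follows: single tokens
(`BP`, `Ma`, `BCE`, …) match **case-sensitively against maximal alphabetic
runs** of the value, so `Ma` hits "Miocene, 18 Ma tuff" and "16Ma" (digit
boundary) but never "Mammal" or "Madagascar", and `BC` never hits "BCE" or
"BCove". Multi-word cues ("dating method") use case-insensitive substring
matching. A raw-substring mode can be configured, but token mode is the
default precisely because of the false-hit families above.

## The synthetic fixtures

Real aggregator snapshots are external, versioned and enormous, so the
package generates its own test worlds:

* **Presets** emulate three published record patterns *in the style of*
  the exemplar use cases — a full AMS radiocarbon chain, an evidence
  synthesis with CE calendar bounds and no assay fields, and a two-assay
  bracket publishing two one-sided records against one occurrence. Values
  are synthetic; they are constructed to validate cleanly, which the tests
  verify rather than assume.
* **The legacy corpus** emulates the statistical shape of a desk-scale
  audit: 95% FossilSpecimen records, filler values drawn from a fixed
  small lexicon (chosen to contain no search token as an alphabetic run),
  planted chronometric strings at per-field rates, and decoy strings that
  look dangerous to naive substring matching. The default plant rates
  (0.0144 for `dynamicProperties`, 0.0032 for `identificationRemarks`,
  0.037 for `lithostratigraphicTerms`, zero for both event-date fields)
  echo the observed sparsity pattern in aggregated fossil-specimen data,
  where explicit chronometry hides in remarks and stratigraphy fields but
  not in `eventDate`. Every planted value embeds a unique serial, so the
  ground truth — the count of distinct matching values per field — is
  known exactly from the plant bookkeeping, never by running the scanner
  on its own output. Generation is a pure function of `(spec, seed)` with
  a private RNG stream that never disturbs the caller's `.Random.seed`.

What passing the planted-recovery property shows: the scanner's
aggregation, filtering and token matching are exact on a corpus whose
ground truth is known. What it does not show: recall on real legacy text,
whose spelling of ages is far more varied than any template vocabulary.
The scanner is a triage tool; `extract_candidates()` exists because a
curator must read the matches.

## Numerical and testing choices

* Problem sizes are chosen for tight feedback loops while still exceeding
  the regimes where the checked properties could pass by accident: the
  calendar oracle grid covers ~12,000 (value, system) pairs spanning
  BCE 1–5000, CE 1–1950, BP 0–5×10⁴, ka/Ma 0–10³; overlap is checked on
  1,000 random integer interval pairs within ±5,000 years against the
  rasterization brute force; round-trips run over all presets plus 1,000
  randomized records whose text exercises tabs, quotes, newlines and
  non-ASCII; the planted-recovery corpus holds 10,000 records.
* Round-trip equality for `from_canonical` is asserted to 1e-9 relative
  tolerance (floating division by the scale factors); everything else in
  the chronology is exact integer-like arithmetic and asserted identical.
* Ages overflowing double precision (`1e999`) are treated as unparseable
  rather than infinite — an infinite age would satisfy "numeric" while
  still corrupting every query.
* Registry definitions are stored byte-verbatim from the ratified source
  (including its typography — note the source's spelling
  "latestChronometicAge" inside one definition); comparisons collapse
  whitespace only.

## Known limitations

* No radiocarbon calibration, age-depth or Bayesian age modelling: the
  package stores assay outputs and their conversion metadata but never
  converts uncalibrated ages itself.
* The ABCD EFG equivalence strings in the registry are stored, not
  interpreted.
* The archive writer targets the ChronometricAge extension; other
  extensions are preserved opaquely on read but not written.
* Geological-stage vocabularies ("Miocene") are not parsed into ages; only
  explicit numeric reference systems are convertible.
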