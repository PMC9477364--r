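# Deterministic synthetic fixtures: three exemplar record patterns and a
# messy legacy corpus with planted chronometric strings and exact ground
# truth.  Exemplar values are *in the style of* the published use cases
# (an AMS-dated shell midden, an evidence-synthesis mission site, a
# twice-bracketed Miocene locality); they are synthetic, not copies of any
# deposited dataset.

occurrence_row <- function(id, scientificName = "", locality = "",
                           eventDate = "", verbatimEventDate = "",
                           dynamicProperties = "",
                           identificationRemarks = "",
                           lithostratigraphicTerms = "",
                           basisOfRecord = "FossilSpecimen") {
  tibble::tibble(
    id = id, occurrenceID = id, basisOfRecord = basisOfRecord,
    scientificName = scientificName, locality = locality,
    eventDate = eventDate, verbatimEventDate = verbatimEventDate,
    dynamicProperties = dynamicProperties,
    identificationRemarks = identificationRemarks,
    lithostratigraphicTerms = lithostratigraphicTerms
  )
}

preset_north_midden <- function() {
  rec <- chronometric_age_record(
    coreReference = "NM-FEAT17-001",
    chronometricAgeID = "NM-CA-1",
    chronometricAgeReferences = "synthetic exemplar dataset, shell midden series",
    materialDated = "right valve of Crassostrea virginica from Feature 17",
    materialDatedID = "IGSN:CHR000001",
    materialDatedRelationship = "dated material from the same archaeological feature as the subject specimen",
    chronometricAgeProtocol = "AMS radiocarbon dating",
    uncalibratedChronometricAge = "3040 +/- 30 14C yr BP",
    chronometricAgeConversionProtocol = "calibrated with OxCal 4.3 using IntCal13",
    earliestChronometricAge = "3360",
    earliestChronometricAgeReferenceSystem = "cal BP",
    latestChronometricAge = "3165",
    latestChronometricAgeReferenceSystem = "cal BP",
    chronometricAgeUncertaintyInYears = "30",
    chronometricAgeUncertaintyMethod = "1-sigma counting error reported by the AMS laboratory",
    chronometricAgeDeterminedBy = "R. Quinn | AMS Laboratory",
    chronometricAgeDeterminedDate = "2015-03-10"
  )
  occ <- occurrence_row(
    "NM-FEAT17-001",
    scientificName = "Crassostrea virginica",
    locality = "North Midden style shell midden, Florida",
    eventDate = "1987-06",
    dynamicProperties = embed_dynamic_properties(rec)
  )
  list(occurrence = occ, chronometric_ages = rec)
}

preset_baptizing_springs <- function() {
  rec <- chronometric_age_record(
    coreReference = "BS-STRUCT2-014",
    chronometricAgeID = "BS-CA-1",
    chronometricAgeReferences = "historical documentation of Spanish mission sites | Spanish ceramic typology references",
    chronometricAgeRemarks = "age from synthesis of documentary and artifact evidence; no assay performed",
    chronometricAgeProtocol = "evidence synthesis from historical documents and ceramic seriation",
    verbatimChronometricAge = "AD 1612-1630",
    earliestChronometricAge = "1612",
    earliestChronometricAgeReferenceSystem = "CE",
    latestChronometricAge = "1630",
    latestChronometricAgeReferenceSystem = "CE",
    chronometricAgeDeterminedBy = "zooarchaeology working group",
    chronometricAgeDeterminedDate = "2018"
  )
  occ <- occurrence_row(
    "BS-STRUCT2-014",
    scientificName = "Sus scrofa",
    locality = "Baptizing Springs style mission site, Florida",
    eventDate = "1979-04-20",
    dynamicProperties = embed_dynamic_properties(rec)
  )
  list(occurrence = occ, chronometric_ages = rec)
}

preset_hawk_rim <- function() {
  rec1 <- chronometric_age_record(
    coreReference = "HR-LOC1-088",
    chronometricAgeID = "HR-CA-1",
    materialDated = "volcanic tuff underlying the fossil horizon",
    materialDatedID = "IGSN:CHR000101",
    materialDatedRelationship = "stratigraphically below the subject specimen",
    chronometricAgeProtocol = "40Ar/39Ar dating of volcanic tuff",
    chronometricAgeRemarks = "older bracket of the locality age range",
    earliestChronometricAge = "16.16",
    earliestChronometricAgeReferenceSystem = "Ma",
    chronometricAgeDeterminedBy = "argon geochronology laboratory",
    chronometricAgeDeterminedDate = "2016-05"
  )
  rec2 <- chronometric_age_record(
    coreReference = "HR-LOC1-088",
    chronometricAgeID = "HR-CA-2",
    materialDated = "zircon crystals from the capping ignimbrite",
    materialDatedID = "IGSN:CHR000102",
    materialDatedRelationship = "stratigraphically above the subject specimen",
    chronometricAgeProtocol = "U-Pb dating of zircon",
    chronometricAgeRemarks = "younger bracket of the locality age range",
    latestChronometricAge = "15.8",
    latestChronometricAgeReferenceSystem = "Ma",
    chronometricAgeDeterminedBy = "U-Pb geochronology laboratory",
    chronometricAgeDeterminedDate = "2016-11"
  )
  recs <- rbind(rec1, rec2)
  occ <- occurrence_row(
    "HR-LOC1-088",
    scientificName = "Merychippus sp.",
    locality = "Hawk Rim style Miocene locality, Oregon",
    eventDate = "2012-08-03",
    lithostratigraphicTerms = "Mascall Formation",
    dynamicProperties = embed_dynamic_properties(recs)
  )
  list(occurrence = occ, chronometric_ages = recs)
}

#' Exemplar ChronometricAge fixtures
#'
#' Builds one of three synthetic exemplar patterns:
#' \describe{
#'   \item{north_midden}{one occurrence, one record: a full AMS radiocarbon
#'     chain (material dated, assay protocol, uncalibrated output,
#'     conversion protocol, calibrated bounds in cal BP, uncertainty,
#'     determination metadata).}
#'   \item{baptizing_springs}{one occurrence, one record: an evidence
#'     synthesis with a verbatim age, references, and CE calendar bounds --
#'     no assay fields.}
#'   \item{hawk_rim}{one occurrence, two records: two assays on two
#'     materials, each contributing a one-sided bound, jointly bracketing
#'     the specimen's age -- the many-records-per-occurrence pattern.}
#' }
#' All presets validate with zero ERROR issues, and each occurrence carries
#' a JSON copy of its records in dynamicProperties.
#'
#' @param name One of `"north_midden"`, `"baptizing_springs"`, `"hawk_rim"`.
#' @return A list with elements `occurrence` (tibble) and
#'   `chronometric_ages` (record tibble).
#' @export
#' @examples
#' make_preset("hawk_rim")$chronometric_ages$chronometricAgeID
make_preset <- function(name) {
  switch(name,
    north_midden = preset_north_midden(),
    baptizing_springs = preset_baptizing_springs(),
    hawk_rim = preset_hawk_rim(),
    chrono_abort(
      sprintf("unknown preset '%s' (known: north_midden, baptizing_springs, hawk_rim)",
              name),
      "chrono_configuration_error"
    )
  )
}

#' Preset names
#' @return Character vector of the exemplar preset names.
#' @export
preset_names <- function() c("north_midden", "baptizing_springs", "hawk_rim")

# ---------------------------------------------------------------------------
# Legacy corpus generation

# Filler lexicons contain no default search token as a maximal alphabetic run
# and never the phrase "dating method".
FILLER <- list(
  eventDate = c("1998-07-14", "1964-03-02", "2003-11-30", "1951-06-01",
                "1987-09-12", "1979-04-20"),
  verbatimEventDate = c("July 1998", "summer of 1964", "late Nov. 2003",
                        "spring field season 1951", "Sept. 1987"),
  dynamicProperties = c('{"preparator": "J. Smith"}',
                        '{"sieved": "yes", "mesh": "2mm"}',
                        '{"loanStatus": "on loan"}',
                        '{"cabinet": "12B"}'),
  identificationRemarks = c("Mammal bone fragment", "left femur, juvenile",
                            "surface find, weathered",
                            "Madagascar comparative series",
                            "cf. genus level only", "partial carapace"),
  lithostratigraphicTerms = c("Mascall Formation", "Bone Valley Formation",
                              "Alachua Formation", "upper shell bed",
                              "unnamed terrace gravels", "Ogallala Group")
)

# Plant templates: each takes a serial and returns a value guaranteed to
# contain at least one default search term.
default_plant_templates <- function() {
  list(
    eventDate = c("1200 BCE (lot %05d)"),
    verbatimEventDate = c("ca. 3200 BP (lot %05d)"),
    dynamicProperties = c(
      '{"chronometricAge":[{"earliestChronometricAge":%d,"earliestChronometricAgeReferenceSystem":"BP"}]}',
      '{"age":"about 16 Ma","lot":"%05d"}',
      '{"dating method":"AMS","lot":"%05d"}'
    ),
    identificationRemarks = c(
      "cf. Bison, dated to 11500 BP (lab AA-%05d)",
      "associated with 1200 BCE horizon (lot %05d)"
    ),
    lithostratigraphicTerms = c(
      "Miocene tuff, ~16 Ma (bed %05d)",
      "Pleistocene terrace, 21 Kya (unit %05d)",
      "upper unit, 2 Mya (section %05d)"
    )
  )
}

DECOY_TEMPLATES <- c("Mammal assemblage lot %05d",
                     "Madagascar reference series %05d",
                     "BCove survey point %05d")

#' Specification of a synthetic legacy corpus
#'
#' Describes a messy occurrence corpus that emulates, at desk scale, the
#' sparsity structure of aggregator snapshots: most values are mundane
#' filler; a small known fraction of records per field receives a planted
#' chronometric string built from the default search tokens; decoy strings
#' ("Mammal", "Madagascar", "BCove") that must never match under token mode
#' are salted in.  Generation is a pure function of (spec, seed).
#'
#' @param n_records Number of occurrence records.
#' @param seed Integer seed; identical (spec, seed) gives byte-identical
#'   corpora.
#' @param plant_rates Named fractions of records per targeted field that
#'   receive a planted matching value.  The defaults (`dynamicProperties`
#'   0.0144, `identificationRemarks` 0.0032, `lithostratigraphicTerms`
#'   0.037, the two event-date fields 0) echo the sparsity pattern observed
#'   in aggregated FossilSpecimen data, where explicit chronometry hides in
#'   remarks and stratigraphy fields but never in eventDate.
#' @param plant_templates Named list of sprintf templates (one `%d`-style
#'   serial slot each), every template containing at least one default
#'   search term.
#' @param decoy_rate Fraction of records per field receiving a decoy value.
#' @param preset_mix Named fractions (`north_midden`, `baptizing_springs`,
#'   `hawk_rim`) of records that carry an exemplar-style JSON payload in
#'   dynamicProperties; these payloads match (they contain reference-system
#'   tokens) and are counted in the ground truth.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_records = 10000L,
                        seed = 20210112L,
                        plant_rates = c(
                          eventDate = 0,
                          verbatimEventDate = 0,
                          dynamicProperties = 0.0144,
                          identificationRemarks = 0.0032,
                          lithostratigraphicTerms = 0.037
                        ),
                        plant_templates = default_plant_templates(),
                        decoy_rate = 0.005,
                        preset_mix = c(north_midden = 0,
                                       baptizing_springs = 0,
                                       hawk_rim = 0)) {
  stopifnot(n_records >= 0, all(plant_rates >= 0), all(plant_rates <= 1),
            decoy_rate >= 0, decoy_rate <= 1,
            all(preset_mix >= 0), sum(preset_mix) <= 1)
  structure(
    list(n_records = as.integer(n_records), seed = as.integer(seed),
         plant_rates = plant_rates, plant_templates = plant_templates,
         decoy_rate = decoy_rate, preset_mix = preset_mix),
    class = "corpus_spec"
  )
}

#' Generate a messy legacy occurrence corpus with exact ground truth
#'
#' Builds `spec$n_records` occurrence records (95% FossilSpecimen, 5%
#' PreservedSpecimen), fills targeted fields with filler from a fixed small
#' lexicon, then plants chronometric strings into FossilSpecimen rows at the
#' per-field rates.  Every planted value embeds a unique serial, so the
#' number of distinct matching values per field is known exactly by
#' construction -- that count is returned as the ground truth, computed from
#' the plant bookkeeping alone, never by running the scanner.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `records` (occurrence tibble), `ground_truth` (named
#'   integer: planted matching unique values per targeted field) and `spec`.
#' @export
#' @examples
#' corpus <- make_legacy_corpus(corpus_spec(n_records = 200, seed = 7))
#' corpus$ground_truth
make_legacy_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_records
  fields <- DEFAULT_TARGET_FIELDS
  with_private_seed(spec$seed, {
    basis <- rep("FossilSpecimen", n)
    if (n > 0L) {
      n_other <- floor(0.05 * n)
      if (n_other > 0L) {
        basis[sample.int(n, n_other)] <- "PreservedSpecimen"
      }
    }
    fossil_rows <- which(basis == "FossilSpecimen")

    cols <- list(
      id = sprintf("LEG-%06d", seq_len(n)),
      occurrenceID = sprintf("LEG-%06d", seq_len(n)),
      basisOfRecord = basis,
      scientificName = if (n) sample(c("Bison antiquus", "Equus sp.",
                                       "Odocoileus virginianus",
                                       "Testudines indet.",
                                       "Crassostrea virginica"),
                                     n, replace = TRUE) else character(0),
      locality = if (n) sample(c("river bluff exposure", "quarry pit 3",
                                 "shell midden unit A", "cave entrance talus"),
                               n, replace = TRUE) else character(0)
    )

    truth <- stats::setNames(integer(length(fields)), fields)
    serial <- 0L
    next_serial <- function() {
      serial <<- serial + 1L
      serial
    }

    for (field in fields) {
      vals <- rep("", n)
      # sparse filler: roughly 60% of rows carry a mundane value
      if (n > 0L) {
        filled <- stats::runif(n) < 0.6
        vals[filled] <- sample(FILLER[[field]], sum(filled), replace = TRUE)
      }
      available <- fossil_rows
      # plants
      n_plant <- as.integer(round((spec$plant_rates[[field]] %||% 0) * n))
      n_plant <- min(n_plant, length(available))
      if (n_plant > 0L) {
        rows <- sample(available, n_plant)
        available <- setdiff(available, rows)
        templates <- spec$plant_templates[[field]]
        for (r in rows) {
          vals[r] <- sprintf(sample(templates, 1L), next_serial())
        }
        truth[[field]] <- truth[[field]] + n_plant
      }
      # decoys (never matching, never in ground truth)
      n_decoy <- as.integer(round(spec$decoy_rate * n))
      n_decoy <- min(n_decoy, length(available))
      if (n_decoy > 0L) {
        rows <- sample(available, n_decoy)
        for (r in rows) {
          vals[r] <- sprintf(sample(DECOY_TEMPLATES, 1L), next_serial())
        }
      }
      cols[[field]] <- vals
    }

    # exemplar-style JSON payloads in dynamicProperties
    dp_available <- fossil_rows[!nzchar(cols$dynamicProperties[fossil_rows])]
    for (preset in names(spec$preset_mix)) {
      n_preset <- as.integer(round(spec$preset_mix[[preset]] * n))
      n_preset <- min(n_preset, length(dp_available))
      if (n_preset == 0L) next
      rows <- sample(dp_available, n_preset)
      dp_available <- setdiff(dp_available, rows)
      base <- make_preset(preset)$chronometric_ages
      for (r in rows) {
        recs <- base
        recs$chronometricAgeID <- sprintf("%s-%05d", recs$chronometricAgeID,
                                          next_serial())
        cols$dynamicProperties[r] <- embed_dynamic_properties(recs)
      }
      truth[["dynamicProperties"]] <- truth[["dynamicProperties"]] + n_preset
    }

    list(records = tibble::as_tibble(cols), ground_truth = truth,
         spec = spec)
  })
}

# ---------------------------------------------------------------------------
# Mutation corruptions for the validator's rule suite

#' Issue codes with a generating corruption
#' @return Character vector of the 12 validation issue codes, each of which
#'   [apply_corruption()] can inject into a clean fixture.
#' @export
corruption_codes <- function() VALIDATION_CODES$code

#' Inject the generating corruption for one issue code
#'
#' Takes a clean fixture (by default the north_midden preset validates with
#' zero issues) and applies the minimal corruption whose detection is the
#' given issue code: e.g. a thousands separator for `NON_NUMERIC_AGE`,
#' swapped bounds for `INVERTED_AGE_BOUNDS`, an unlinked `coreReference` for
#' `ORPHAN_EXTENSION_ROW`.  Used by the mutation suite to show each rule
#' fires exactly, and only, on its own corruption.
#'
#' @param fixture A list with `occurrence` and `chronometric_ages`, as
#'   returned by [make_preset()].
#' @param code One of [corruption_codes()].
#' @return The corrupted fixture (same shape).
#' @export
apply_corruption <- function(fixture, code) {
  occ <- fixture$occurrence
  recs <- fixture$chronometric_ages
  set <- function(field, value) recs[[field]][1L] <<- value
  switch(code,
    NON_NUMERIC_AGE = set("earliestChronometricAge", "3,360"),
    INVERTED_AGE_BOUNDS = {
      e <- recs$earliestChronometricAge[1L]
      set("earliestChronometricAge", recs$latestChronometricAge[1L])
      set("latestChronometricAge", e)
    },
    NEGATIVE_UNCERTAINTY = set("chronometricAgeUncertaintyInYears", "-30"),
    BAD_DETERMINED_DATE = set("chronometricAgeDeterminedDate", "March 2015"),
    AGE_WITHOUT_REFERENCE_SYSTEM =
      set("earliestChronometricAgeReferenceSystem", ""),
    REFERENCE_SYSTEM_WITHOUT_AGE = set("earliestChronometricAge", ""),
    UNPARSEABLE_REFERENCE_SYSTEM =
      set("earliestChronometricAgeReferenceSystem", "fortnights"),
    UNCAL_WITHOUT_CONVERSION_PROTOCOL =
      set("chronometricAgeConversionProtocol", ""),
    FUTURE_AGE = set("latestChronometricAge", "-10"),
    EMPTY_RECORD = {
      for (nm in CHRONO_PROPERTY_TERMS) set(nm, "")
    },
    ORPHAN_EXTENSION_ROW = set("coreReference", "UNLINKED-999"),
    DUPLICATE_CHRONOMETRIC_AGE_ID = {
      dup <- recs[1L, ]
      dup$chronometricAgeRemarks <- "duplicate identifier on purpose"
      recs <- rbind(recs, dup)
    },
    chrono_abort(sprintf("unknown corruption code '%s'", code),
                 "chrono_configuration_error")
  )
  list(occurrence = occ, chronometric_ages = recs)
}
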