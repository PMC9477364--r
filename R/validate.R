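# Quality-flag validation for ChronometricAge records.
#
# Severity policy: anything that would corrupt a temporal query is ERROR;
# anything that merely reduces interpretability is WARNING or INFO.  The
# standard mandates no field, so hard failures are reserved for
# self-contradiction; validation itself never throws on content.

VALIDATION_CODES <- tibble::tibble(
  code = c(
    "NON_NUMERIC_AGE", "INVERTED_AGE_BOUNDS", "NEGATIVE_UNCERTAINTY",
    "BAD_DETERMINED_DATE", "AGE_WITHOUT_REFERENCE_SYSTEM",
    "REFERENCE_SYSTEM_WITHOUT_AGE", "UNPARSEABLE_REFERENCE_SYSTEM",
    "UNCAL_WITHOUT_CONVERSION_PROTOCOL", "FUTURE_AGE", "EMPTY_RECORD",
    "ORPHAN_EXTENSION_ROW", "DUPLICATE_CHRONOMETRIC_AGE_ID"
  ),
  severity = c(
    "ERROR", "ERROR", "ERROR", "ERROR", "WARNING", "WARNING", "WARNING",
    "INFO", "WARNING", "WARNING", "ERROR", "WARNING"
  ),
  level = c(rep("record", 10L), rep("dataset", 2L))
)

#' The closed set of validation issue codes
#'
#' @return A tibble with columns `code`, `severity` and `level` (record vs
#'   dataset) describing every issue the validator can raise.
#' @export
issue_codes <- function() VALIDATION_CODES

new_issue <- function(code, term = "", message = "", recordRef = "") {
  sev <- VALIDATION_CODES$severity[match(code, VALIDATION_CODES$code)]
  tibble::tibble(severity = sev, code = code, term = term,
                 message = message, recordRef = recordRef)
}

no_issues <- function() {
  tibble::tibble(severity = character(0), code = character(0),
                 term = character(0), message = character(0),
                 recordRef = character(0))
}

record_ref <- function(rec) {
  id <- trimws(chrono_chr(rec[["chronometricAgeID"]] %||% ""))
  if (nzchar(id)) id else trimws(chrono_chr(rec[["coreReference"]] %||% ""))
}

#' Validate one ChronometricAge record
#'
#' Applies the conditional rule set that makes "no required fields" safe to
#' consume.  Rules (severity in brackets):
#' \describe{
#'   \item{NON_NUMERIC_AGE [ERROR]}{an age bound or uncertainty is present
#'     but not parseable as a number (thousands separators are rejected).}
#'   \item{INVERTED_AGE_BOUNDS [ERROR]}{after normalization to the canonical
#'     axis the older bound is younger than the younger bound.}
#'   \item{NEGATIVE_UNCERTAINTY [ERROR]}{`chronometricAgeUncertaintyInYears`
#'     is negative.}
#'   \item{BAD_DETERMINED_DATE [ERROR]}{`chronometricAgeDeterminedDate` is
#'     not an ISO 8601 date, year, or "/"-separated interval.}
#'   \item{AGE_WITHOUT_REFERENCE_SYSTEM [WARNING]}{a numeric bound has no
#'     paired reference system.}
#'   \item{REFERENCE_SYSTEM_WITHOUT_AGE [WARNING]}{a reference system has no
#'     paired bound.}
#'   \item{UNPARSEABLE_REFERENCE_SYSTEM [WARNING]}{a stated reference system
#'     is not recognized.}
#'   \item{UNCAL_WITHOUT_CONVERSION_PROTOCOL [INFO]}{an uncalibrated assay
#'     output coexists with calibrated bounds but no conversion protocol is
#'     reported.}
#'   \item{FUTURE_AGE [WARNING]}{a normalized bound falls after 1950.}
#'   \item{EMPTY_RECORD [WARNING]}{every property term is empty.}
#' }
#' Validation never raises on record content.
#'
#' @param rec A ChronometricAge record (one-row tibble or named list of
#'   field text).
#' @param registry Term registry used to enumerate the property terms.
#' @return A tibble of validation issues (zero rows means conformant) with
#'   columns `severity`, `code`, `term`, `message`, `recordRef`.
#' @export
#' @examples
#' validate_record(chronometric_age_record())           # EMPTY_RECORD
#' validate_record(chronometric_age_record(
#'   earliestChronometricAge = "500",
#'   earliestChronometricAgeReferenceSystem = "BP",
#'   latestChronometricAge = "1000",
#'   latestChronometricAgeReferenceSystem = "BP"
#' ))                                                   # INVERTED_AGE_BOUNDS
validate_record <- function(rec, registry = chrono_registry()) {
  rec <- as.list(rec)
  prop_terms <- setdiff(recommended_terms(registry)$localName,
                        CHRONO_CLASS_TERM)
  if (!length(prop_terms)) prop_terms <- CHRONO_PROPERTY_TERMS
  get1 <- function(nm) trimws(chrono_chr(rec[[nm]] %||% "")[1L])
  ref <- record_ref(rec)
  issues <- list()
  add <- function(code, term = "", message = "") {
    issues[[length(issues) + 1L]] <<- new_issue(code, term, message, ref)
  }

  vals <- vapply(prop_terms, get1, character(1))
  if (all(!nzchar(vals))) {
    add("EMPTY_RECORD", "", "all property terms are empty")
    return(do.call(rbind, issues))
  }

  # numeric parses
  nums <- list()
  for (nm in intersect(CHRONO_NUMERIC_TERMS, prop_terms)) {
    txt <- get1(nm)
    if (!nzchar(txt)) { nums[[nm]] <- NA_real_; next }
    v <- parse_age_number(txt)
    if (is.na(v)) {
      add("NON_NUMERIC_AGE", nm, sprintf("'%s' is not a number", txt))
    }
    nums[[nm]] <- v
  }

  u <- nums[["chronometricAgeUncertaintyInYears"]]
  if (!is.null(u) && !is.na(u) && u < 0) {
    add("NEGATIVE_UNCERTAINTY", "chronometricAgeUncertaintyInYears",
        sprintf("uncertainty %g is negative", u))
  }

  dd <- get1("chronometricAgeDeterminedDate")
  if (nzchar(dd) && !is_iso8601_date(dd)) {
    add("BAD_DETERMINED_DATE", "chronometricAgeDeterminedDate",
        sprintf("'%s' is not an ISO 8601 date or date range", dd))
  }

  # bound / reference-system pairing, and canonical normalization
  canon <- list(earliest = NULL, latest = NULL)
  for (side in c("earliest", "latest")) {
    age_term <- paste0(side, "ChronometricAge")
    rs_term <- paste0(side, "ChronometricAgeReferenceSystem")
    age_txt <- get1(age_term)
    rs_txt <- get1(rs_term)
    has_age <- nzchar(age_txt)
    has_rs <- nzchar(rs_txt)
    if (has_age && !has_rs) {
      add("AGE_WITHOUT_REFERENCE_SYSTEM", age_term,
          sprintf("%s has no paired reference system", age_term))
    }
    if (has_rs && !has_age) {
      add("REFERENCE_SYSTEM_WITHOUT_AGE", rs_term,
          sprintf("%s has no paired age", rs_term))
    }
    rs <- if (has_rs) parse_reference_system(rs_txt) else NULL
    if (has_rs && rs$kind == "UNKNOWN") {
      add("UNPARSEABLE_REFERENCE_SYSTEM", rs_term,
          sprintf("'%s' is not a recognized reference system", rs_txt))
    }
    v <- nums[[age_term]]
    if (has_age && !is.null(v) && !is.na(v) && !is.null(rs) && rs$convertible) {
      canon[[side]] <- to_canonical(v, rs)
      if (canon[[side]] < 0) {
        add("FUTURE_AGE", age_term,
            sprintf("%s normalizes to %g yr BP (after 1950)",
                    age_term, canon[[side]]))
      }
    }
  }
  if (!is.null(canon$earliest) && !is.null(canon$latest) &&
      canon$earliest < canon$latest) {
    add("INVERTED_AGE_BOUNDS", "earliestChronometricAge",
        sprintf("older bound %g yr BP is younger than %g yr BP",
                canon$earliest, canon$latest))
  }

  has_bound <- any(nzchar(c(get1("earliestChronometricAge"),
                            get1("latestChronometricAge"))))
  if (nzchar(get1("uncalibratedChronometricAge")) && has_bound &&
      !nzchar(get1("chronometricAgeConversionProtocol"))) {
    add("UNCAL_WITHOUT_CONVERSION_PROTOCOL", "chronometricAgeConversionProtocol",
        "uncalibrated assay output reported alongside calibrated bounds without a conversion protocol")
  }

  if (length(issues)) do.call(rbind, issues) else no_issues()
}

#' Validate a dataset of core occurrences plus extension records
#'
#' Unions per-record issues with dataset-level linkage checks:
#' `ORPHAN_EXTENSION_ROW` (ERROR) when a record's `coreReference` matches no
#' core identifier, and `DUPLICATE_CHRONOMETRIC_AGE_ID` (WARNING) when one
#' non-empty `chronometricAgeID` appears on distinct records.  Multiple
#' extension rows per core occurrence are first-class in the star schema and
#' raise nothing.
#'
#' @param core Core occurrence identifiers: a character vector, or a data
#'   frame with an `id` column.
#' @param exts ChronometricAge records (tibble, one row each).
#' @param registry Term registry passed through to [validate_record()].
#' @return A tibble of validation issues.
#' @export
validate_dataset <- function(core, exts, registry = chrono_registry()) {
  if (is.data.frame(core)) core <- core[["id"]]
  core <- chrono_chr(core)
  exts <- as_chronometric_age_records(exts)
  issues <- list()
  for (i in seq_len(nrow(exts))) {
    issues[[length(issues) + 1L]] <- validate_record(exts[i, ], registry)
  }
  orphan <- !exts$coreReference %in% core
  for (i in which(orphan)) {
    issues[[length(issues) + 1L]] <- new_issue(
      "ORPHAN_EXTENSION_ROW", "coreReference",
      sprintf("coreReference '%s' matches no core identifier",
              exts$coreReference[i]),
      record_ref(exts[i, ])
    )
  }
  ids <- exts$chronometricAgeID
  ids <- ids[nzchar(trimws(ids))]
  for (dup in unique(ids[duplicated(ids)])) {
    issues[[length(issues) + 1L]] <- new_issue(
      "DUPLICATE_CHRONOMETRIC_AGE_ID", "chronometricAgeID",
      sprintf("chronometricAgeID '%s' appears on multiple records", dup),
      dup
    )
  }
  if (length(issues)) do.call(rbind, issues) else no_issues()
}
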