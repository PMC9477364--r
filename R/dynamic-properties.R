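# JSON dialect for carrying ChronometricAge data inside dwc:dynamicProperties,
# so ages stay visible in flat occurrence downloads where extension files are
# not shown.  Envelope: {"chronometricAge": [ {...}, ... ]} -- always an
# array, because many records per occurrence are first-class; a bare object
# is still accepted on read.

#' Embed ChronometricAge records as dynamicProperties JSON
#'
#' Serializes the records of one occurrence into the package's
#' dynamicProperties dialect.  Member keys are term local names in standard
#' order; only non-empty fields are serialized.  Numeric fields whose text
#' form survives a number round-trip losslessly are emitted as JSON numbers,
#' anything else as strings; the output never contains NaN or Infinity.
#'
#' @param records ChronometricAge records (tibble) all sharing one
#'   `coreReference`.
#' @return A single JSON string.
#' @section Errors:
#' `chrono_consistency_error` if records carry mixed `coreReference` values.
#' @export
#' @examples
#' embed_dynamic_properties(chronometric_age_record(
#'   earliestChronometricAge = 1000,
#'   earliestChronometricAgeReferenceSystem = "BP"
#' ))
embed_dynamic_properties <- function(records) {
  records <- as_chronometric_age_records(records)
  refs <- unique(records$coreReference)
  if (length(refs) > 1L) {
    chrono_abort(
      sprintf("records carry mixed coreReference values: %s",
              paste(refs, collapse = ", ")),
      "chrono_consistency_error"
    )
  }
  members <- lapply(seq_len(nrow(records)), function(i) {
    row <- as.list(records[i, ])
    out <- list()
    for (nm in CHRONO_PROPERTY_TERMS) {
      v <- chrono_chr(row[[nm]])
      if (!nzchar(v)) next
      if (nm %in% CHRONO_NUMERIC_TERMS) {
        num <- parse_age_number(v)
        if (!is.na(num) && identical(fmt_field(num), trimws(v))) {
          out[[nm]] <- num
          next
        }
      }
      out[[nm]] <- v
    }
    out
  })
  as.character(jsonlite::toJSON(list(chronometricAge = members),
                                auto_unbox = TRUE, digits = NA))
}

#' Extract ChronometricAge records from dynamicProperties text
#'
#' Tolerant reader for the `"chronometricAge"` member of a
#' dwc:dynamicProperties payload.  A JSON object is treated as a singleton,
#' an array as many records; sibling keys (other dynamic properties) pass
#' through untouched; unknown keys inside a member are ignored with an
#' `UNKNOWN_TERM` warning note; non-JSON input yields an empty result plus a
#' parse warning note.  Never raises.
#'
#' @param dynamic_properties The text content of dwc:dynamicProperties.
#' @return A ChronometricAge record tibble (possibly zero rows) with an
#'   attribute `"warnings"`: a character vector of accumulated warning
#'   notes.
#' @export
extract_dynamic_properties <- function(dynamic_properties) {
  notes <- character(0)
  empty <- chronometric_age_records()
  txt <- chrono_chr(dynamic_properties)[1L]
  if (!nzchar(trimws(txt))) {
    return(structure(empty, warnings = notes))
  }
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) e
  )
  if (inherits(parsed, "error") || !is.list(parsed)) {
    notes <- c(notes, sprintf("PARSE: dynamicProperties is not a JSON object (%s)",
                              if (inherits(parsed, "error"))
                                conditionMessage(parsed) else "scalar"))
    return(structure(empty, warnings = notes))
  }
  payload <- parsed[["chronometricAge"]]
  if (is.null(payload)) {
    return(structure(empty, warnings = notes))
  }
  # object -> singleton, array -> many
  members <- if (is.list(payload) && !is.null(names(payload))) list(payload)
             else if (is.list(payload)) payload
             else {
               notes <- c(notes, "PARSE: chronometricAge member is not an object or array")
               list()
             }
  rows <- list()
  for (m in members) {
    if (!is.list(m)) {
      notes <- c(notes, "PARSE: skipping non-object chronometricAge member")
      next
    }
    unknown <- setdiff(names(m), CHRONO_PROPERTY_TERMS)
    if (length(unknown)) {
      notes <- c(notes, sprintf("UNKNOWN_TERM: %s",
                                paste(unknown, collapse = ", ")))
    }
    known <- intersect(names(m), CHRONO_PROPERTY_TERMS)
    args <- lapply(m[known], function(v) {
      if (is.null(v)) "" else fmt_field(v)
    })
    rows[[length(rows) + 1L]] <- do.call(
      chronometric_age_record, c(list(coreReference = ""), args)
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, warnings = notes)
}

#' Accumulated warnings of a tolerant read
#' @param x Result of [extract_dynamic_properties()].
#' @return Character vector of warning notes (possibly empty).
#' @export
extraction_warnings <- function(x) attr(x, "warnings") %||% character(0)

#' Check archive extension rows against their embedded JSON copy
#'
#' When the same ages are published both as extension rows and as JSON in
#' dwc:dynamicProperties, the two copies can drift.  Records are matched by
#' `chronometricAgeID` when both sides carry one, positionally otherwise;
#' fields are compared after whitespace normalization, numerically for the
#' numeric terms.  Differences yield `EMBEDDED_MISMATCH` warnings naming the
#' term; a count difference yields an `EMBEDDED_CARDINALITY` warning.
#'
#' @param archive_records Extension-row records of one core occurrence.
#' @param embedded_records Records extracted from that occurrence's
#'   dynamicProperties.
#' @return A tibble of validation issues (empty when the copies agree).
#' @export
check_embedded_consistency <- function(archive_records, embedded_records) {
  a <- as_chronometric_age_records(archive_records)
  b <- as_chronometric_age_records(embedded_records)
  issues <- no_issues()
  mk <- function(code, severity, term, message, ref) {
    tibble::tibble(severity = severity, code = code, term = term,
                   message = message, recordRef = ref)
  }
  if (nrow(a) != nrow(b)) {
    issues <- rbind(issues, mk(
      "EMBEDDED_CARDINALITY", "WARNING", "",
      sprintf("%d extension record(s) vs %d embedded record(s)",
              nrow(a), nrow(b)),
      if (nrow(a)) a$coreReference[1L] else ""
    ))
  }
  ids_a <- trimws(a$chronometricAgeID)
  ids_b <- trimws(b$chronometricAgeID)
  use_ids <- all(nzchar(ids_a)) && all(nzchar(ids_b)) &&
    !anyDuplicated(ids_a) && !anyDuplicated(ids_b)
  pairs <- if (use_ids) {
    common <- intersect(ids_a, ids_b)
    cbind(match(common, ids_a), match(common, ids_b))
  } else {
    n <- min(nrow(a), nrow(b))
    cbind(seq_len(n), seq_len(n))
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- a[pairs[k, 1L], ]
    rb <- b[pairs[k, 2L], ]
    for (nm in CHRONO_PROPERTY_TERMS) {
      va <- collapse_ws(ra[[nm]])
      vb <- collapse_ws(rb[[nm]])
      same <- if (nm %in% CHRONO_NUMERIC_TERMS &&
                  !is.na(parse_age_number(va)) && !is.na(parse_age_number(vb))) {
        isTRUE(parse_age_number(va) == parse_age_number(vb))
      } else {
        identical(va, vb)
      }
      if (!same) {
        issues <- rbind(issues, mk(
          "EMBEDDED_MISMATCH", "WARNING", nm,
          sprintf("extension has '%s', embedded copy has '%s'", va, vb),
          record_ref(ra)
        ))
      }
    }
  }
  issues
}
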