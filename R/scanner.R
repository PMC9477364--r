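# Field audit scanner: finds chronometric-age content hiding in
# non-chronometric Darwin Core fields and reports per-field unique-value and
# match counts.  Counting is over unique values, not record occurrences:
# values are aggregated per field first, then matched.

# Darwin Core occurrence terms accepted as scan targets.  Not exhaustive --
# just the terms plausibly carrying free text or dates in occurrence data.
KNOWN_DWC_FIELDS <- c(
  "eventDate", "verbatimEventDate", "dynamicProperties",
  "identificationRemarks", "lithostratigraphicTerms", "occurrenceRemarks",
  "fieldNotes", "georeferenceRemarks", "taxonRemarks", "locationRemarks",
  "eventRemarks", "habitat", "samplingProtocol", "verbatimLocality",
  "formation", "member", "bed", "group", "earliestAgeOrLowestStage",
  "latestAgeOrHighestStage", "associatedReferences", "basisOfRecord",
  "scientificName", "locality"
)

DWC_FIELD_ALIASES <- c(verbatimEvent = "verbatimEventDate")

DEFAULT_TARGET_FIELDS <- c(
  "eventDate", "verbatimEventDate", "dynamicProperties",
  "identificationRemarks", "lithostratigraphicTerms"
)

DEFAULT_TOKENS <- c("BCE", "BC", "CE", "AD", "BP", "Ky", "Kya", "My", "Ma",
                    "Mya")
DEFAULT_PHRASES <- "dating method"

#' Build a search-term set for the field scanner
#'
#' Two match modes are supported.  `TOKEN_CASE_SENSITIVE` matches a token
#' against the maximal alphabetic runs of a value, case-sensitively, so
#' "Ma" hits "Miocene, 18 Ma tuff" but never "Mammal", and "BC" never hits
#' "BCE".  `PHRASE_CASE_INSENSITIVE` is a plain case-insensitive substring
#' match, used for multi-word cues like "dating method".
#'
#' @param tokens Character vector of case-sensitive tokens.
#' @param phrases Character vector of case-insensitive phrases.
#' @param fields Targeted Darwin Core field names; the alias
#'   `verbatimEvent` is accepted for `verbatimEventDate`.
#' @return An object of class `search_term_set`.
#' @section Errors:
#' `chrono_configuration_error` listing the known Darwin Core terms when a
#' targeted field is not recognized.
#' @export
search_term_set <- function(tokens = character(0), phrases = character(0),
                            fields = DEFAULT_TARGET_FIELDS) {
  fields <- vapply(fields, function(f) {
    if (f %in% names(DWC_FIELD_ALIASES)) DWC_FIELD_ALIASES[[f]] else f
  }, character(1), USE.NAMES = FALSE)
  unknown <- setdiff(fields, KNOWN_DWC_FIELDS)
  if (length(unknown)) {
    chrono_abort(
      sprintf("unknown targeted field(s): %s; known Darwin Core terms: %s",
              paste(unknown, collapse = ", "),
              paste(sort(KNOWN_DWC_FIELDS), collapse = ", ")),
      "chrono_configuration_error"
    )
  }
  structure(
    list(
      tokens = tibble::tibble(
        text = c(tokens, phrases),
        matchMode = c(rep("TOKEN_CASE_SENSITIVE", length(tokens)),
                      rep("PHRASE_CASE_INSENSITIVE", length(phrases)))
      ),
      targetedFields = fields
    ),
    class = "search_term_set"
  )
}

#' Default chronometry search terms
#'
#' The stock audit configuration: tokens "BCE", "BC", "CE", "AD", "BP",
#' "Ky", "Kya", "My", "Ma", "Mya" (token mode) plus the phrase
#' "dating method" (case-insensitive), over the five fields where providers
#' are known to stash temporal information: eventDate, verbatimEventDate,
#' dynamicProperties, identificationRemarks, lithostratigraphicTerms.
#'
#' @return A `search_term_set` with 11 search terms over 5 targeted fields.
#' @export
#' @examples
#' default_search_terms()
default_search_terms <- function() {
  search_term_set(tokens = DEFAULT_TOKENS, phrases = DEFAULT_PHRASES,
                  fields = DEFAULT_TARGET_FIELDS)
}

#' @export
print.search_term_set <- function(x, ...) {
  cat(sprintf("<search_term_set: %d term(s) over %d field(s)>\n",
              nrow(x$tokens), length(x$targetedFields)))
  invisible(x)
}

match_values <- function(values, term_text, mode) {
  if (mode == "PHRASE_CASE_INSENSITIVE") {
    grepl(tolower(term_text), tolower(values), fixed = TRUE)
  } else {
    runs <- strsplit(values, "[^A-Za-z]+")
    vapply(runs, function(r) term_text %in% r, logical(1))
  }
}

#' Audit occurrence records for chronometric content
#'
#' Restricts the corpus to one `basisOfRecord` class (default
#' `"FossilSpecimen"`), aggregates the distinct non-empty trimmed values of
#' each targeted field, and counts how many distinct values match at least
#' one search term.
#'
#' @param records Occurrence tibble (columns named by Darwin Core local
#'   names; targeted fields may be absent).
#' @param terms A `search_term_set`; defaults to [default_search_terms()].
#' @param basis_filter `basisOfRecord` value to restrict to, or `NULL` to
#'   scan every record.
#' @param keep_evidence Retain the matched values themselves so
#'   [extract_candidates()] can list them.
#' @return An object of class `scan_report`: `recordsScanned` plus, per
#'   field, `uniqueValueCount`, `matchedValueCount`, `perTermCounts` and
#'   (when retained) the matched values with their matching terms.
#' @export
scan_occurrences <- function(records, terms = default_search_terms(),
                             basis_filter = "FossilSpecimen",
                             keep_evidence = TRUE) {
  stopifnot(inherits(terms, "search_term_set"))
  records <- tibble::as_tibble(records)
  if (!is.null(basis_filter)) {
    basis <- if ("basisOfRecord" %in% names(records)) {
      trimws(chrono_chr(records$basisOfRecord))
    } else {
      rep("", nrow(records))
    }
    records <- records[basis == basis_filter, , drop = FALSE]
  }

  per_field <- list()
  for (field in terms$targetedFields) {
    values <- if (field %in% names(records)) {
      trimws(chrono_chr(records[[field]]))
    } else {
      character(0)
    }
    values <- unique(values[nzchar(values)])
    hit_any <- rep(FALSE, length(values))
    per_term <- integer(nrow(terms$tokens))
    names(per_term) <- terms$tokens$text
    hit_terms <- vector("list", length(values))
    for (k in seq_len(nrow(terms$tokens))) {
      hits <- match_values(values, terms$tokens$text[k],
                           terms$tokens$matchMode[k])
      per_term[k] <- sum(hits)
      hit_any <- hit_any | hits
      for (i in which(hits)) {
        hit_terms[[i]] <- c(hit_terms[[i]], terms$tokens$text[k])
      }
    }
    evidence <- NULL
    if (keep_evidence) {
      evidence <- tibble::tibble(
        value = values[hit_any],
        terms = vapply(hit_terms[hit_any], paste, character(1),
                       collapse = ", ")
      )
    }
    per_field[[field]] <- list(
      uniqueValueCount = length(values),
      matchedValueCount = sum(hit_any),
      perTermCounts = per_term,
      matchedValues = evidence
    )
  }

  structure(
    list(recordsScanned = nrow(records), perField = per_field,
         evidenceRetained = keep_evidence),
    class = "scan_report"
  )
}

#' Summarize a scan report as a table
#'
#' @param report A `scan_report`.
#' @return A tibble with one row per targeted field: `field`,
#'   `uniqueValueCount`, `matchedValueCount`.
#' @export
scan_summary <- function(report) {
  stopifnot(inherits(report, "scan_report"))
  tibble::tibble(
    field = names(report$perField),
    uniqueValueCount = vapply(report$perField, `[[`, integer(1),
                              "uniqueValueCount"),
    matchedValueCount = vapply(report$perField, function(f) {
      as.integer(f$matchedValueCount)
    }, integer(1))
  )
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report over %d record(s)>\n", x$recordsScanned))
  print(scan_summary(x))
  invisible(x)
}

#' List matched values for curator triage
#'
#' Deterministic evidence listing: one row per matched unique value, ordered
#' by field then value (byte order, locale-independent), truncated at
#' `limit`.
#'
#' @param report A `scan_report` built with `keep_evidence = TRUE`.
#' @param limit Maximum number of rows.
#' @return A tibble with columns `field`, `value`, `terms`.
#' @section Errors:
#' `chrono_state_error` if the report was built without evidence retention.
#' @export
extract_candidates <- function(report, limit = 100L) {
  stopifnot(inherits(report, "scan_report"))
  if (!isTRUE(report$evidenceRetained)) {
    chrono_abort("scan report was built without evidence retention",
                 "chrono_state_error")
  }
  rows <- lapply(names(report$perField), function(field) {
    ev <- report$perField[[field]]$matchedValues
    if (is.null(ev) || nrow(ev) == 0L) return(NULL)
    tibble::tibble(field = field, value = ev$value, terms = ev$terms)
  })
  out <- do.call(rbind, c(rows, list(tibble::tibble(
    field = character(0), value = character(0), terms = character(0)
  ))))
  out <- out[order(out$field, out$value, method = "radix"), , drop = FALSE]
  utils::head(out, limit)
}
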