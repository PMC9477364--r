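#' Load a ChronometricAge term-version registry
#'
#' The extension vocabulary is maintained, Darwin Core style, as a CSV with a
#' row for each version of a term: identifier, preferred label, definition,
#' whether the version is recommended for current use, an ABCD EFG equivalence
#' string (stored, never interpreted) and free-text notes.  With no argument
#' the bundled snapshot of the ratified vocabulary is loaded, so offline use
#' always works.
#'
#' Definitions are stored byte-verbatim from the ratified source (including
#' its typography); normalization happens only at comparison time.
#'
#' @param source Path to a term-version CSV (UTF-8, header row, RFC-4180
#'   quoting), or a data frame with equivalent columns.  `NULL` loads the
#'   bundled snapshot.
#' @param columns Named list mapping the registry's logical fields to the
#'   header names used by `source`.  Recognized logical names:
#'   `identifier`, `localName`, `label`, `definition`, `versionDate`,
#'   `recommended`, `abcdEquivalence`, `notes`.  `localName` may be omitted,
#'   in which case it is derived from the identifier IRI.
#'
#' @return An object of class `chrono_term_registry`: a list with elements
#'   `terms` (a tibble of all term versions) and `classTerm` (the recommended
#'   row for the class term `chronometricAge`).
#'
#' @section Errors:
#' A missing definition (or identifier/recommended) column raises a
#' `chrono_format_error`.  Two recommended versions of one local name, or a
#' registry with no recommended class term, raise a
#' `chrono_registry_conflict` error.
#'
#' @export
#' @examples
#' reg <- load_term_registry()
#' nrow(recommended_terms(reg))
load_term_registry <- function(source = NULL,
                               columns = list(
                                 identifier = "term_iri",
                                 localName = "term_localName",
                                 label = "label",
                                 definition = "definition",
                                 versionDate = "issued",
                                 recommended = "status",
                                 abcdEquivalence = "abcd_equivalence",
                                 notes = "notes"
                               )) {
  if (is.null(source)) {
    source <- system.file("extdata", "term_versions.csv",
                          package = "chronoage", mustWork = TRUE)
  }
  if (is.character(source)) {
    tab <- utils::read.csv(source, colClasses = "character",
                           check.names = FALSE, encoding = "UTF-8")
  } else {
    tab <- as.data.frame(source, stringsAsFactors = FALSE)
  }

  need <- c("identifier", "definition", "recommended")
  for (logical_name in need) {
    header <- columns[[logical_name]]
    if (is.null(header) || !header %in% names(tab)) {
      chrono_abort(
        sprintf("term-version table lacks a column for '%s' (expected header '%s')",
                logical_name, header %||% "<unset>"),
        "chrono_format_error"
      )
    }
  }

  pick <- function(logical_name, default = "") {
    header <- columns[[logical_name]]
    if (!is.null(header) && header %in% names(tab)) chrono_chr(tab[[header]])
    else rep(default, nrow(tab))
  }

  iri <- trimws(pick("identifier"))
  local_name <- trimws(pick("localName"))
  if (all(!nzchar(local_name))) local_name <- basename(iri)
  local_name[!nzchar(local_name)] <- basename(iri[!nzchar(local_name)])
  rec_raw <- tolower(trimws(pick("recommended")))
  recommended <- rec_raw %in% c("recommended", "true", "yes", "1")

  terms <- tibble::tibble(
    iri = iri,
    localName = local_name,
    label = pick("label"),
    definition = pick("definition"),
    versionDate = pick("versionDate"),
    recommended = recommended,
    abcdEquivalence = pick("abcdEquivalence"),
    notes = pick("notes")
  )

  new_term_registry(terms)
}

new_term_registry <- function(terms) {
  rec <- terms[terms$recommended, , drop = FALSE]
  dup <- unique(rec$localName[duplicated(rec$localName)])
  if (length(dup)) {
    chrono_abort(
      sprintf("duplicate recommended versions of term(s): %s",
              paste(dup, collapse = ", ")),
      "chrono_registry_conflict"
    )
  }
  # class terms capitalize the leading letter in the IRI (DwC convention),
  # so the suffix check is case-insensitive
  bad_iri <- rec$localName[!mapply(endsWith, tolower(rec$iri),
                                   tolower(rec$localName))]
  if (length(bad_iri)) {
    chrono_abort(
      sprintf("term IRI does not end with its local name: %s",
              paste(bad_iri, collapse = ", ")),
      "chrono_registry_conflict"
    )
  }
  no_def <- rec$localName[!nzchar(trimws(rec$definition))]
  if (length(no_def)) {
    chrono_abort(
      sprintf("recommended term(s) lack a definition: %s",
              paste(no_def, collapse = ", ")),
      "chrono_registry_conflict"
    )
  }
  cls <- rec[rec$localName == CHRONO_CLASS_TERM, , drop = FALSE]
  if (nrow(cls) != 1L) {
    chrono_abort(
      "registry has no recommended class term 'chronometricAge'",
      "chrono_registry_conflict"
    )
  }
  structure(list(terms = terms, classTerm = cls),
            class = "chrono_term_registry")
}

#' @export
print.chrono_term_registry <- function(x, ...) {
  rec <- x$terms[x$terms$recommended, , drop = FALSE]
  cat(sprintf("<chrono_term_registry: %d term versions, %d recommended>\n",
              nrow(x$terms), nrow(rec)))
  cat(paste0("  ", rec$localName, collapse = "\n"), "\n")
  invisible(x)
}

#' Recommended terms of a registry
#'
#' @param registry A `chrono_term_registry`.
#' @return A tibble with one row per recommended term, in registry order.
#' @export
recommended_terms <- function(registry) {
  stopifnot(inherits(registry, "chrono_term_registry"))
  registry$terms[registry$terms$recommended, , drop = FALSE]
}

# Memoized bundled registry; loading is cheap but the validator calls it per
# record.
the <- new.env(parent = emptyenv())

#' Bundled registry of the ratified vocabulary
#'
#' @return The `chrono_term_registry` loaded from the bundled snapshot
#'   (cached after the first call).
#' @export
chrono_registry <- function() {
  if (is.null(the$registry)) the$registry <- load_term_registry()
  the$registry
}

#' Resolve a term by local name or IRI
#'
#' Lookup is case-sensitive on local names (Darwin Core local names are
#' camelCase and case-significant).  A key matching only a deprecated version
#' resolves to that version with a warning (`chrono_deprecated_term`) rather
#' than an error, because archives in the wild may predate ratification.
#'
#' @param registry A `chrono_term_registry`.
#' @param key A term local name (e.g. `"materialDated"`) or full IRI.
#' @return A one-row tibble describing the term version.
#' @export
#' @examples
#' resolve_term(chrono_registry(), "materialDatedRelationship")$definition
resolve_term <- function(registry, key) {
  stopifnot(inherits(registry, "chrono_term_registry"), is.character(key),
            length(key) == 1L)
  terms <- registry$terms
  hit <- terms$localName == key | terms$iri == key
  rec_hit <- terms[hit & terms$recommended, , drop = FALSE]
  if (nrow(rec_hit)) return(rec_hit[1L, , drop = FALSE])
  dep_hit <- terms[hit & !terms$recommended, , drop = FALSE]
  if (nrow(dep_hit)) {
    warning(warningCondition(
      sprintf("term '%s' resolves only to a deprecated version", key),
      class = "chrono_deprecated_term"
    ))
    return(dep_hit[1L, , drop = FALSE])
  }
  chrono_abort(sprintf("unknown term: '%s'", key), "chrono_unknown_term",
               key = key)
}

#' Serialize a term registry back to CSV
#'
#' Writes the registry in the bundled snapshot's column layout (UTF-8, header
#' row, RFC-4180 quoting), so `load_term_registry(write_term_registry(r, p))`
#' is an identity.
#'
#' @param registry A `chrono_term_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_term_registry <- function(registry, path) {
  stopifnot(inherits(registry, "chrono_term_registry"))
  t <- registry$terms
  out <- data.frame(
    term_iri = t$iri,
    term_localName = t$localName,
    label = t$label,
    definition = t$definition,
    issued = t$versionDate,
    status = ifelse(t$recommended, "recommended", "superseded"),
    abcd_equivalence = t$abcdEquivalence,
    notes = t$notes,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
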