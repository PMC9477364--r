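#' Construct ChronometricAge records
#'
#' A ChronometricAge record is one row of the extension: the 18 ratified
#' property terms plus `coreReference`, the linkage key to the core
#' occurrence (the archive `coreid`).  Every field is individually optional
#' -- the standard mandates nothing -- so all fields default to the empty
#' string and are stored as text, exactly as they travel in a Darwin Core
#' Archive.  Numeric fields are parsed at the point of use.
#'
#' Records are plain tibbles with a fixed column set, so collections of
#' records are just row-bound tibbles.
#'
#' @param coreReference Identifier of the linked core occurrence record.
#' @param ... Values for property terms, by name (see
#'   [chronometric_age_terms()]).  Unnamed or unknown names are an error.
#' @return A one-row tibble with columns `coreReference` plus the 18
#'   property terms, all character.
#' @export
#' @examples
#' chronometric_age_record(
#'   coreReference = "OCC-1",
#'   earliestChronometricAge = 1000,
#'   earliestChronometricAgeReferenceSystem = "BP"
#' )
chronometric_age_record <- function(coreReference = "", ...) {
  extra <- list(...)
  if (length(extra)) {
    nms <- names(extra)
    if (is.null(nms) || any(!nzchar(nms))) {
      chrono_abort("all record fields must be named", "chrono_domain_error")
    }
    unknown <- setdiff(nms, CHRONO_PROPERTY_TERMS)
    if (length(unknown)) {
      chrono_abort(
        sprintf("unknown ChronometricAge term(s): %s",
                paste(unknown, collapse = ", ")),
        "chrono_unknown_term", key = unknown
      )
    }
  }
  row <- stats::setNames(
    as.list(rep("", length(CHRONO_PROPERTY_TERMS) + 1L)),
    c("coreReference", CHRONO_PROPERTY_TERMS)
  )
  row$coreReference <- fmt_field(coreReference)
  for (nm in names(extra)) row[[nm]] <- fmt_field(extra[[nm]])
  tibble::as_tibble(row)
}

# Numbers become their plain decimal text form; everything else is passed
# through as character.
fmt_field <- function(x) {
  if (length(x) == 0L) return("")
  if (is.numeric(x)) {
    out <- format(x, scientific = FALSE, trim = TRUE, digits = 15)
  } else {
    out <- as.character(x)
  }
  out <- out[1L]
  if (is.na(out)) "" else out
}

#' Coerce a data frame to a ChronometricAge record collection
#'
#' Keeps recognized term columns (plus `coreReference`), fills missing ones
#' with empty strings and restores standard column order.  Unrecognized
#' columns are dropped.
#'
#' @param df A data frame whose columns are term local names.
#' @return A tibble with the canonical record columns, all character.
#' @export
as_chronometric_age_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  cols <- c("coreReference", CHRONO_PROPERTY_TERMS)
  out <- lapply(cols, function(nm) {
    if (nm %in% names(df)) chrono_chr(df[[nm]]) else rep("", nrow(df))
  })
  names(out) <- cols
  tibble::as_tibble(out)
}

#' An empty ChronometricAge record collection
#' @return A zero-row tibble with the canonical record columns.
#' @export
chronometric_age_records <- function() {
  as_chronometric_age_records(
    stats::setNames(
      as.data.frame(matrix(character(0), nrow = 0,
                           ncol = length(CHRONO_PROPERTY_TERMS) + 1L),
                    stringsAsFactors = FALSE),
      c("coreReference", CHRONO_PROPERTY_TERMS)
    )
  )
}
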