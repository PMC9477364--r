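#' Parse an age reference-system label
#'
#' Chronometric ages arrive against heterogeneous reference systems: years
#' before present (BP, with the conventional 1950 CE datum), historical
#' calendar labels (BCE/BC, CE/AD), and scaled before-present units
#' (ka, Ma, Ga).  This parser classifies a verbatim label into one of those
#' kinds, case-insensitively after trimming.  It is total: unrecognized
#' labels yield kind `UNKNOWN` (never an error), and uncalibrated radiocarbon
#' labels ("uncal BP", "14C yr BP") yield kind `UNCAL_C14`.  Both of those
#' kinds are flagged non-convertible: raw radiocarbon years are not calendar
#' years and must never be placed on the calendar axis without an explicit
#' calibration, which is out of scope here.
#'
#' @param label Verbatim reference-system text (may be empty).
#' @return An object of class `chrono_reference_system`: a list with fields
#'   `label`, `kind` (one of BP, BCE, CE, KA, MA, GA, UNCAL_C14, UNKNOWN),
#'   `scaleYears` (1, 1e3, 1e6 or 1e9), `datumYearCE` (1950 for
#'   before-present kinds, `NA` otherwise) and `convertible`.
#' @export
#' @examples
#' parse_reference_system("cal BP")$kind
#' parse_reference_system("Mya")$scaleYears
#' parse_reference_system("uncal BP")$convertible
parse_reference_system <- function(label) {
  stopifnot(length(label) == 1L)
  raw <- chrono_chr(label)
  key <- tolower(trimws(raw))

  kind <-
    if (grepl("uncal", key, fixed = TRUE)) "UNCAL_C14"
    else if ((grepl("14c", key, fixed = TRUE) ||
              grepl("radiocarbon", key, fixed = TRUE)) &&
             grepl("bp", key, fixed = TRUE)) "UNCAL_C14"
    else if (key %in% c("bp", "cal bp", "years bp")) "BP"
    else if (key %in% c("bce", "bc")) "BCE"
    else if (key %in% c("ce", "ad")) "CE"
    else if (key %in% c("ka", "kya", "ky")) "KA"
    else if (key %in% c("ma", "mya", "my")) "MA"
    else if (key == "ga") "GA"
    else "UNKNOWN"

  scale <- switch(kind, KA = 1e3, MA = 1e6, GA = 1e9, 1)
  datum <- if (kind %in% c("BP", "KA", "MA", "GA")) 1950 else NA_real_
  structure(
    list(
      label = raw,
      kind = kind,
      scaleYears = scale,
      datumYearCE = datum,
      convertible = !kind %in% c("UNCAL_C14", "UNKNOWN")
    ),
    class = "chrono_reference_system"
  )
}

#' @export
print.chrono_reference_system <- function(x, ...) {
  cat(sprintf("<reference system '%s': kind=%s scale=%g convertible=%s>\n",
              x$label, x$kind, x$scaleYears, x$convertible))
  invisible(x)
}

#' Map ages to the canonical timeline
#'
#' The package's canonical axis is real-valued calendar years before 1950 CE
#' (the BP datum), larger = older; ages after 1950 are negative.  BCE/CE
#' labels are converted through astronomical year numbering with no year
#' zero: CE year y has astronomical year y, BCE year y has astronomical year
#' 1 - y, and the canonical age is 1950 minus the astronomical year.  ka, Ma
#' and Ga are treated as before-present with the 1950 datum (the <=50-year
#' datum offset is far below the precision of such ages).
#'
#' @param value Numeric age value(s) expressed in `rs` units.
#' @param rs A `chrono_reference_system` (or a label passed to
#'   [parse_reference_system()]).
#' @return Numeric canonical age(s) in calendar years before 1950.
#' @export
#' @examples
#' to_canonical(1950, parse_reference_system("CE"))   # 0
#' to_canonical(100, parse_reference_system("BCE"))   # 2049
#' to_canonical(1, parse_reference_system("Ma"))      # 1e6
to_canonical <- function(value, rs) {
  if (is.character(rs)) rs <- parse_reference_system(rs)
  stopifnot(inherits(rs, "chrono_reference_system"))
  if (!rs$convertible) {
    chrono_abort(
      sprintf("reference system of kind %s cannot be placed on the canonical axis",
              rs$kind),
      "chrono_not_convertible", kind = rs$kind
    )
  }
  value <- as.numeric(value)
  if (any(!is.finite(value))) {
    chrono_abort("age value must be finite", "chrono_domain_error")
  }
  switch(rs$kind,
    BP = value,
    KA = ,
    MA = ,
    GA = value * rs$scaleYears,
    CE = 1950 - value,
    BCE = 1950 - (1 - value)
  )
}

#' Invert the canonical mapping
#'
#' @param canonical Canonical age(s) in calendar years before 1950.
#' @inheritParams to_canonical
#' @return Numeric value(s) expressed in `rs` units, such that
#'   `to_canonical(from_canonical(x, rs), rs) == x`.
#' @export
from_canonical <- function(canonical, rs) {
  if (is.character(rs)) rs <- parse_reference_system(rs)
  stopifnot(inherits(rs, "chrono_reference_system"))
  if (!rs$convertible) {
    chrono_abort(
      sprintf("reference system of kind %s cannot be placed on the canonical axis",
              rs$kind),
      "chrono_not_convertible", kind = rs$kind
    )
  }
  canonical <- as.numeric(canonical)
  if (any(!is.finite(canonical))) {
    chrono_abort("canonical age must be finite", "chrono_domain_error")
  }
  switch(rs$kind,
    BP = canonical,
    KA = ,
    MA = ,
    GA = canonical / rs$scaleYears,
    CE = 1950 - canonical,
    BCE = canonical - 1949
  )
}

#' Age intervals on the canonical axis
#'
#' An interval holds the older (earliest possible) and younger (latest
#' possible) bounds of a chronometric age, both in canonical years before
#' 1950.  `older >= younger` is enforced.
#'
#' @param older,younger Canonical ages (years before 1950).
#' @param one_sided Whether the interval came from a record with only one
#'   bound (stored degenerate, `older == younger`).
#' @return An object of class `age_interval`.
#' @export
#' @examples
#' age_interval(1000, 500)
age_interval <- function(older, younger, one_sided = FALSE) {
  stopifnot(is.numeric(older), is.numeric(younger),
            length(older) == 1L, length(younger) == 1L)
  if (!is.finite(older) || !is.finite(younger)) {
    chrono_abort("interval bounds must be finite", "chrono_domain_error")
  }
  if (older < younger) {
    chrono_abort(
      sprintf("inverted interval: older bound %g < younger bound %g",
              older, younger),
      "chrono_inverted_interval"
    )
  }
  structure(list(older = older, younger = younger,
                 one_sided = isTRUE(one_sided)),
            class = "age_interval")
}

#' @export
print.age_interval <- function(x, ...) {
  cat(sprintf("<age interval: %g .. %g yr BP%s>\n", x$older, x$younger,
              if (x$one_sided) " (one-sided)" else ""))
  invisible(x)
}

#' Canonical age interval of a ChronometricAge record
#'
#' Normalizes a record's `earliestChronometricAge` / `latestChronometricAge`
#' pair onto the canonical axis, each bound interpreted against its own
#' reference system (the two systems may differ).  A record with only one
#' bound yields a degenerate one-sided interval at that bound rather than an
#' unbounded one.
#'
#' @param rec A ChronometricAge record (one-row tibble or named list; see
#'   [chronometric_age_record()]).
#' @return An `age_interval`.
#' @section Errors:
#' `chrono_empty_record` if neither bound is present;
#' `chrono_domain_error` if a present bound is not parseable as a number;
#' `chrono_not_convertible` if a present bound's reference system is
#' unknown or uncalibrated radiocarbon;
#' `chrono_inverted_interval` if the normalized older bound is younger than
#' the normalized younger bound (the dataset validator downgrades this to a
#' quality issue; direct callers get the error).
#' @export
interval_from_record <- function(rec) {
  rec <- as.list(rec)
  get1 <- function(nm) trimws(chrono_chr(rec[[nm]] %||% "")[1L])
  e_txt <- get1("earliestChronometricAge")
  l_txt <- get1("latestChronometricAge")
  if (!nzchar(e_txt) && !nzchar(l_txt)) {
    chrono_abort("record carries no numeric age bound", "chrono_empty_record")
  }
  bound <- function(txt, rs_field) {
    v <- parse_age_number(txt)
    if (is.na(v)) {
      chrono_abort(sprintf("age bound '%s' is not a number", txt),
                   "chrono_domain_error")
    }
    to_canonical(v, parse_reference_system(get1(rs_field)))
  }
  if (nzchar(e_txt) && nzchar(l_txt)) {
    older <- bound(e_txt, "earliestChronometricAgeReferenceSystem")
    younger <- bound(l_txt, "latestChronometricAgeReferenceSystem")
    age_interval(older, younger)
  } else if (nzchar(e_txt)) {
    x <- bound(e_txt, "earliestChronometricAgeReferenceSystem")
    age_interval(x, x, one_sided = TRUE)
  } else {
    x <- bound(l_txt, "latestChronometricAgeReferenceSystem")
    age_interval(x, x, one_sided = TRUE)
  }
}

#' Expand an interval by a symmetric uncertainty
#'
#' Widens an interval by `uncertainty_years` on both sides, the semantics of
#' `chronometricAgeUncertaintyInYears`.  The younger bound may cross the 1950
#' datum and become negative; no clamping is applied (the validator flags
#' post-1950 bounds as a warning, not an error).
#'
#' @param iv An `age_interval`.
#' @param uncertainty_years Non-negative number of calendar years.
#' @return An `age_interval` whose width is exactly `2 * uncertainty_years`
#'   larger.
#' @export
#' @examples
#' expand_uncertainty(age_interval(1000, 500), 30)
expand_uncertainty <- function(iv, uncertainty_years) {
  stopifnot(inherits(iv, "age_interval"))
  u <- as.numeric(uncertainty_years)
  if (length(u) != 1L || !is.finite(u) || u < 0) {
    chrono_abort("uncertainty must be a single non-negative number",
                 "chrono_domain_error")
  }
  age_interval(iv$older + u, iv$younger - u,
               one_sided = iv$one_sided && u == 0)
}

#' Do two age intervals overlap?
#'
#' Closed-interval semantics: endpoint contact counts as overlap.  The
#' intended use is recall-biased chronological search ("give me everything
#' that could fall in this window"), where missing a boundary record is
#' worse than returning it.
#'
#' @param a,b `age_interval` objects.
#' @return `TRUE` iff the closed intervals intersect.
#' @export
#' @examples
#' overlaps(age_interval(1000, 500), age_interval(500, 200))  # TRUE
overlaps <- function(a, b) {
  stopifnot(inherits(a, "age_interval"), inherits(b, "age_interval"))
  a$older >= b$younger && b$older >= a$younger
}
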