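# Internal parsing helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

chrono_chr <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

# Strict numeric parsing: optional sign, decimal point, scientific notation.
# Thousands separators ("3,040") are deliberately rejected -- locale-dependent
# parsing silently corrupts ages.
parse_age_number <- function(x) {
  x <- trimws(chrono_chr(x))
  ok <- grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)
  out <- rep(NA_real_, length(x))
  out[ok] <- as.numeric(x[ok])
  out[!is.finite(out)] <- NA_real_  # overflow like 1e999 is not a usable age
  out
}

# ISO 8601 calendar dates at year, month or day precision, optionally a
# "/"-separated interval of two such dates (Darwin Core eventDate practice).
is_iso8601_date <- function(x) {
  one <- function(d) {
    if (!grepl("^[0-9]{4}(-[0-9]{2}(-[0-9]{2})?)?$", d)) return(FALSE)
    parts <- strsplit(d, "-", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) {
      m <- as.integer(parts[2L])
      if (m < 1L || m > 12L) return(FALSE)
    }
    if (length(parts) == 3L) {
      day <- as.integer(parts[3L])
      if (day < 1L || day > 31L) return(FALSE)
      # reject days the month cannot hold (leap years allowed for Feb 29)
      dim <- c(31L, 29L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
      if (day > dim[m]) return(FALSE)
    }
    TRUE
  }
  vapply(trimws(chrono_chr(x)), function(d) {
    if (!nzchar(d)) return(FALSE)
    pieces <- strsplit(d, "/", fixed = TRUE)[[1]]
    if (length(pieces) < 1L || length(pieces) > 2L) return(FALSE)
    if (grepl("^/|/$", d)) return(FALSE)
    all(vapply(pieces, one, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

collapse_ws <- function(x) trimws(gsub("[[:space:]]+", " ", chrono_chr(x)))

chrono_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "chrono_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Run code with a private RNG stream so generators are pure in (spec, seed)
# and never disturb the caller's .Random.seed.
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}
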