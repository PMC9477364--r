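# Independent oracles, kept deliberately separate from the implementation
# paths they check.

# Historical-calendar oracle: enumerate the label sequence around the missing
# year zero (... 2 BCE, 1 BCE, 1 CE, 2 CE ...) and read canonical ages off a
# lookup table anchored at 1950 CE = 0.
calendar_oracle <- local({
  bce_years <- 5000:1          # labels "5000 BCE" .. "1 BCE", oldest first
  ce_years <- 1:2100           # labels "1 CE" .. "2100 CE"
  n <- length(bce_years) + length(ce_years)
  # consecutive calendar years, so canonical age drops by 1 per step;
  # anchor the youngest entry (2100 CE) at 1950 - 2100 = -150
  canonical <- (1950 - 2100) + (n - seq_len(n))
  list(
    bce = function(y) canonical[match(y, bce_years)],
    ce = function(y) canonical[length(bce_years) + match(y, ce_years)]
  )
})

# Scale oracle for before-present units.
scale_oracle <- function(value, unit) {
  value * switch(unit, BP = 1, KA = 1e3, MA = 1e6, GA = 1e9)
}

# Brute-force overlap oracle: rasterize both intervals at 1-year resolution
# and look for a shared point.  Only valid for integer-bounded intervals.
overlap_bruteforce <- function(a_older, a_younger, b_older, b_younger) {
  length(intersect(seq(a_younger, a_older), seq(b_younger, b_older))) > 0L
}

# Independent token matcher for scanner checks: substring hit whose
# neighbours are non-alphabetic.
token_match_oracle <- function(value, token) {
  starts <- gregexpr(token, value, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(FALSE)
  chars <- strsplit(value, "")[[1L]]
  is_alpha <- function(ch) grepl("[A-Za-z]", ch)
  any(vapply(starts, function(s) {
    before_ok <- s == 1L || !is_alpha(chars[s - 1L])
    e <- s + nchar(token) - 1L
    after_ok <- e == length(chars) || !is_alpha(chars[e + 1L])
    before_ok && after_ok
  }, logical(1)))
}

strip_warnings_attr <- function(x) {
  attr(x, "warnings") <- NULL
  x
}

record_fields_equal <- function(a, b) {
  a <- as.data.frame(strip_warnings_attr(a))[, chronometric_age_terms()]
  b <- as.data.frame(strip_warnings_attr(b))[, chronometric_age_terms()]
  rownames(a) <- rownames(b) <- NULL
  identical(a, b)
}

# Random record generator for property-style round-trip tests.  Numeric
# fields get plain-form numbers; text fields exercise the writer's quoting
# (tabs, quotes, newlines, unicode).
random_record <- function(core_id = "OCC-1") {
  texts <- c("plain value", "tab\there", 'quote " inside', "new\nline",
             "comma, semicolon;", "unicode µm – dash", "  padded  ",
             "pipe | list | of | things", "")
  args <- list(coreReference = core_id)
  for (nm in chronometric_age_terms()) {
    if (runif(1) < 0.4) next
    if (nm %in% c("earliestChronometricAge", "latestChronometricAge",
                  "chronometricAgeUncertaintyInYears")) {
      args[[nm]] <- as.character(sample(0:50000, 1L))
    } else if (endsWith(nm, "ReferenceSystem")) {
      args[[nm]] <- sample(c("BP", "cal BP", "ka", "Ma", "CE", "BCE"), 1L)
    } else if (nm == "chronometricAgeDeterminedDate") {
      args[[nm]] <- sample(c("2015", "2015-03", "2015-03-10",
                             "2014-01-01/2015-12-31"), 1L)
    } else {
      args[[nm]] <- sample(texts, 1L)
    }
  }
  do.call(chronometric_age_record, args)
}

collapse_ws_test <- function(x) trimws(gsub("[[:space:]]+", " ", x))
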