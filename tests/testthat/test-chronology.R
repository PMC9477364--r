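test_that("reference-system labels are classified as specified", {
  cases <- list(
    list("BP", "BP", 1), list("cal BP", "BP", 1), list("years BP", "BP", 1),
    list(" bp ", "BP", 1),
    list("BCE", "BCE", 1), list("BC", "BCE", 1),
    list("CE", "CE", 1), list("AD", "CE", 1),
    list("ka", "KA", 1e3), list("Kya", "KA", 1e3), list("Ky", "KA", 1e3),
    list("Ma", "MA", 1e6), list("Mya", "MA", 1e6), list("My", "MA", 1e6),
    list("Ga", "GA", 1e9)
  )
  for (cs in cases) {
    rs <- parse_reference_system(cs[[1]])
    expect_identical(rs$kind, cs[[2]], info = cs[[1]])
    expect_identical(rs$scaleYears, cs[[3]], info = cs[[1]])
    expect_true(rs$convertible, info = cs[[1]])
  }
  expect_identical(parse_reference_system("BP")$datumYearCE, 1950)
  for (lab in c("uncal BP", "14C yr BP", "radiocarbon years BP")) {
    rs <- parse_reference_system(lab)
    expect_identical(rs$kind, "UNCAL_C14", info = lab)
    expect_false(rs$convertible, info = lab)
  }
  for (lab in c("", "fortnights", "years", "14C")) {
    rs <- parse_reference_system(lab)
    expect_identical(rs$kind, "UNKNOWN", info = lab)
    expect_false(rs$convertible, info = lab)
  }
})

test_that("canonical mapping agrees with the historical-calendar oracle", {
  bce <- parse_reference_system("BCE")
  ce <- parse_reference_system("CE")
  expect_equal(to_canonical(1:5000, bce), calendar_oracle$bce(1:5000))
  expect_equal(to_canonical(1:2100, ce), calendar_oracle$ce(1:2100))
  # spot values
  expect_identical(to_canonical(0, "BP"), 0)
  expect_identical(to_canonical(1950, ce), 0)
  expect_identical(to_canonical(100, bce), 2049)
  expect_identical(to_canonical(1, "Ma"), 1e6)
  # no year zero: 1 BCE and 1 CE are adjacent years
  expect_identical(to_canonical(1, bce) - to_canonical(1, ce), 1)
})

test_that("scaled before-present units multiply onto the canonical axis", {
  vals <- c(0, 0.5, 1, 16.16, 250, 1000)
  for (unit in c("BP", "KA", "MA", "GA")) {
    lab <- switch(unit, BP = "BP", KA = "ka", MA = "Ma", GA = "Ga")
    expect_equal(to_canonical(vals, parse_reference_system(lab)),
                 scale_oracle(vals, unit), info = unit)
  }
})

test_that("non-convertible systems are refused, non-finite values rejected", {
  expect_error(to_canonical(3040, parse_reference_system("uncal BP")),
               class = "chrono_not_convertible")
  expect_error(to_canonical(1, parse_reference_system("gibberish")),
               class = "chrono_not_convertible")
  expect_error(to_canonical(NaN, parse_reference_system("BP")),
               class = "chrono_domain_error")
  expect_error(from_canonical(10, parse_reference_system("uncal BP")),
               class = "chrono_not_convertible")
})

test_that("from_canonical inverts to_canonical on every convertible system", {
  set.seed(42)
  for (lab in c("BP", "ka", "Ma", "Ga", "CE", "BCE")) {
    rs <- parse_reference_system(lab)
    v <- round(runif(200, 1, 5000), 3)
    expect_equal(from_canonical(to_canonical(v, rs), rs), v,
                 tolerance = 1e-9, info = lab)
  }
})

test_that("monotonicity: older ages map to larger canonical values", {
  v <- sort(runif(50, 1, 4000))
  for (lab in c("BP", "ka", "Ma", "BCE")) {
    expect_true(all(diff(to_canonical(v, parse_reference_system(lab))) > 0),
                info = lab)
  }
  expect_true(all(diff(to_canonical(v, parse_reference_system("CE"))) < 0))
})

test_that("record intervals normalize mixed systems and flag one-sided bounds", {
  iv <- interval_from_record(chronometric_age_record(
    earliestChronometricAge = "1000",
    earliestChronometricAgeReferenceSystem = "BP",
    latestChronometricAge = "500",
    latestChronometricAgeReferenceSystem = "BP"
  ))
  expect_equal(c(iv$older, iv$younger), c(1000, 500))
  expect_false(iv$one_sided)

  mixed <- interval_from_record(chronometric_age_record(
    earliestChronometricAge = "2",
    earliestChronometricAgeReferenceSystem = "ka",
    latestChronometricAge = "1500",
    latestChronometricAgeReferenceSystem = "BP"
  ))
  expect_equal(c(mixed$older, mixed$younger), c(2000, 1500))

  one <- interval_from_record(chronometric_age_record(
    earliestChronometricAge = "16.16",
    earliestChronometricAgeReferenceSystem = "Ma"
  ))
  expect_true(one$one_sided)
  expect_equal(one$older, one$younger)
  expect_equal(one$older, 16.16e6)

  expect_error(interval_from_record(chronometric_age_record(
    earliestChronometricAge = "500",
    earliestChronometricAgeReferenceSystem = "BP",
    latestChronometricAge = "1000",
    latestChronometricAgeReferenceSystem = "BP"
  )), class = "chrono_inverted_interval")
  expect_error(interval_from_record(chronometric_age_record()),
               class = "chrono_empty_record")
})

test_that("uncertainty expansion widens by exactly 2u and never clamps", {
  iv <- age_interval(1000, 500)
  expect_identical(expand_uncertainty(iv, 0), iv)
  ex <- expand_uncertainty(iv, 30)
  expect_equal(c(ex$older, ex$younger), c(1030, 470))
  crossing <- expand_uncertainty(age_interval(100, 50), 75)
  expect_equal(c(crossing$older, crossing$younger), c(175, -25))
  expect_error(expand_uncertainty(iv, -1), class = "chrono_domain_error")
  set.seed(7)
  for (i in 1:50) {
    a <- sort(runif(2, -100, 3000))
    u <- runif(1, 0, 500)
    before <- age_interval(a[2], a[1])
    after <- expand_uncertainty(before, u)
    expect_equal((after$older - after$younger) - (before$older - before$younger),
                 2 * u)
  }
})

test_that("overlap matches the 1-year rasterization brute force", {
  expect_true(overlaps(age_interval(1000, 500), age_interval(600, 100)))
  expect_false(overlaps(age_interval(1000, 500), age_interval(400, 100)))
  # shared endpoint counts under closed-interval semantics
  expect_true(overlaps(age_interval(1000, 500), age_interval(500, 200)))
  set.seed(99)
  for (i in 1:300) {
    a <- sort(sample(-5000:5000, 2))
    b <- sort(sample(-5000:5000, 2))
    ia <- age_interval(a[2], a[1])
    ib <- age_interval(b[2], b[1])
    expect_identical(overlaps(ia, ib),
                     overlap_bruteforce(a[2], a[1], b[2], b[1]))
    expect_identical(overlaps(ia, ib), overlaps(ib, ia))  # symmetric
    expect_true(overlaps(ia, ia))                          # reflexive
  }
})
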