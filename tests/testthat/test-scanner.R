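test_that("default search terms reproduce the stock audit configuration", {
  terms <- default_search_terms()
  expect_identical(nrow(terms$tokens), 11L)
  expect_setequal(
    terms$tokens$text[terms$tokens$matchMode == "TOKEN_CASE_SENSITIVE"],
    c("BCE", "BC", "CE", "AD", "BP", "Ky", "Kya", "My", "Ma", "Mya")
  )
  expect_identical(
    terms$tokens$text[terms$tokens$matchMode == "PHRASE_CASE_INSENSITIVE"],
    "dating method"
  )
  expect_false("Ga" %in% terms$tokens$text)
  expect_identical(terms$targetedFields,
                   c("eventDate", "verbatimEventDate", "dynamicProperties",
                     "identificationRemarks", "lithostratigraphicTerms"))
  # the short alias is accepted on input
  alias <- search_term_set(fields = c("verbatimEvent", "eventDate"))
  expect_identical(alias$targetedFields, c("verbatimEventDate", "eventDate"))
  expect_error(search_term_set(fields = "noSuchField"),
               class = "chrono_configuration_error")
})

test_that("token matching is over maximal alphabetic runs, case-sensitively", {
  occ <- tibble::tibble(
    id = as.character(1:6),
    basisOfRecord = "FossilSpecimen",
    lithostratigraphicTerms = c("Miocene, 18 Ma tuff", "Mammal bone",
                                "Madagascar series", "about 16Ma",
                                "maybe 18 ma tuff", "BCove point"),
    identificationRemarks = c("Dating Method: seriation", "", "", "", "", "")
  )
  rep <- scan_occurrences(occ, search_term_set(
    tokens = c("Ma", "BC"),
    phrases = "dating method",
    fields = c("lithostratigraphicTerms", "identificationRemarks")
  ))
  litho <- rep$perField$lithostratigraphicTerms
  expect_identical(litho$uniqueValueCount, 6L)
  # "Ma" hits "18 Ma tuff" and "16Ma" (digit boundary), never "Mammal",
  # "Madagascar", lowercase "ma"; "BC" never hits "BCove"
  expect_identical(litho$matchedValueCount, 2L)
  expect_identical(unname(litho$perTermCounts[["Ma"]]), 2L)
  expect_identical(unname(litho$perTermCounts[["BC"]]), 0L)
  # phrase mode is case-insensitive substring
  expect_identical(rep$perField$identificationRemarks$matchedValueCount, 1L)

  # agreement with an independently coded boundary-checking matcher
  for (v in occ$lithostratigraphicTerms) {
    runs <- strsplit(v, "[^A-Za-z]+")[[1]]
    expect_identical("Ma" %in% runs, token_match_oracle(v, "Ma"), info = v)
  }
})

test_that("counting is over unique values and respects the basis filter", {
  occ <- tibble::tibble(
    id = as.character(1:5),
    basisOfRecord = c("FossilSpecimen", "FossilSpecimen", "FossilSpecimen",
                      "PreservedSpecimen", "FossilSpecimen"),
    lithostratigraphicTerms = c("16 Ma tuff", "16 Ma tuff", "plain bed",
                                "99 Ma should be excluded", "")
  )
  rep <- scan_occurrences(occ)
  litho <- rep$perField$lithostratigraphicTerms
  expect_identical(rep$recordsScanned, 4L)
  expect_identical(litho$uniqueValueCount, 2L)   # duplicates collapse
  expect_identical(litho$matchedValueCount, 1L)  # non-fossil row excluded
  # absent targeted fields simply count zero
  expect_identical(rep$perField$dynamicProperties$uniqueValueCount, 0L)

  empty <- scan_occurrences(occ[0, ])
  expect_true(all(scan_summary(empty)$uniqueValueCount == 0L))
})

test_that("scan counts are duplicate-insensitive and term-monotone", {
  corpus <- make_legacy_corpus(corpus_spec(n_records = 400, seed = 303))
  base <- scan_summary(scan_occurrences(corpus$records))
  doubled <- scan_summary(scan_occurrences(
    rbind(corpus$records, corpus$records)
  ))
  expect_identical(doubled, base)

  fewer <- search_term_set(tokens = c("BP", "Ma"),
                           phrases = character(0))
  more <- search_term_set(tokens = c("BP", "Ma", "BCE", "Kya", "Mya"),
                          phrases = "dating method")
  m_few <- scan_summary(scan_occurrences(corpus$records, fewer))
  m_more <- scan_summary(scan_occurrences(corpus$records, more))
  expect_true(all(m_more$matchedValueCount >= m_few$matchedValueCount))
})

test_that("planted matches are recovered exactly, decoys never match", {
  corpus <- make_legacy_corpus(corpus_spec(n_records = 2000, seed = 77))
  rep <- scan_occurrences(corpus$records)
  for (field in names(corpus$ground_truth)) {
    expect_identical(rep$perField[[field]]$matchedValueCount,
                     corpus$ground_truth[[field]], info = field)
  }
  ev <- extract_candidates(rep, limit = 100000L)
  expect_false(any(grepl("Mammal|Madagascar|BCove", ev$value)))
})

test_that("candidate extraction is deterministic and state-checked", {
  corpus <- make_legacy_corpus(corpus_spec(n_records = 500, seed = 9))
  rep <- scan_occurrences(corpus$records)
  a <- extract_candidates(rep, limit = 10L)
  b <- extract_candidates(scan_occurrences(corpus$records), limit = 10L)
  expect_identical(a, b)
  expect_lte(nrow(a), 10L)
  expect_identical(extract_candidates(rep, limit = 1L), a[1, ])

  blind <- scan_occurrences(corpus$records, keep_evidence = FALSE)
  expect_error(extract_candidates(blind), class = "chrono_state_error")
})
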