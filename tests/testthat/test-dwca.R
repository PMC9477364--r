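sorted_records <- function(recs) {
  recs <- as.data.frame(recs)
  recs <- recs[order(recs$coreReference, recs$chronometricAgeID,
                     recs$chronometricAgeRemarks, method = "radix"), ]
  rownames(recs) <- NULL
  recs
}

test_that("write then read round-trips every preset field-for-field", {
  for (nm in preset_names()) {
    fx <- make_preset(nm)
    dir <- withr::local_tempdir()
    write_archive(fx$occurrence, fx$chronometric_ages, dir)
    arch <- read_archive(dir)
    expect_identical(sorted_records(arch$chronometric_ages),
                     sorted_records(fx$chronometric_ages), info = nm)
    for (col in names(fx$occurrence)) {
      if (col %in% names(arch$occurrences)) {
        expect_identical(arch$occurrences[[col]], fx$occurrence[[col]],
                         info = paste(nm, col))
      } else {
        # only all-empty columns may be dropped by the writer
        expect_true(all(!nzchar(fx$occurrence[[col]])), info = paste(nm, col))
      }
    }
  }
})

test_that("values containing tabs, quotes and newlines survive the dialect", {
  set.seed(5)
  occ <- tibble::tibble(id = sprintf("OCC-%03d", 1:40),
                        basisOfRecord = "FossilSpecimen")
  recs <- do.call(rbind, lapply(1:40, function(i) {
    random_record(sprintf("OCC-%03d", i))
  }))
  dir <- withr::local_tempdir()
  write_archive(occ, recs, dir)
  arch <- read_archive(dir)
  expect_identical(sorted_records(arch$chronometric_ages),
                   sorted_records(recs))
})

test_that("archive without extension rows omits the extension element", {
  occ <- tibble::tibble(id = "A", basisOfRecord = "FossilSpecimen")
  dir <- withr::local_tempdir()
  desc <- write_archive(occ, chronometric_age_records(), dir)
  expect_length(desc$extensions, 0)
  expect_false(file.exists(file.path(dir, "chronometricage.txt")))
  arch <- read_archive(dir)
  expect_identical(nrow(arch$chronometric_ages), 0L)
  expect_identical(arch$occurrences$id, "A")
})

test_that("orphan extension rows are refused unless forced", {
  occ <- tibble::tibble(id = "A")
  rec <- chronometric_age_record(coreReference = "B",
                                 chronometricAgeRemarks = "orphan")
  dir <- withr::local_tempdir()
  expect_error(write_archive(occ, rec, file.path(dir, "x")),
               class = "chrono_consistency_error")
  expect_no_error(write_archive(occ, rec, file.path(dir, "y"), force = TRUE))
})

test_that("reading honors meta.xml indices over header order", {
  dir <- withr::local_tempdir()
  # header deliberately lies: meta.xml says index 1 = scientificName
  writeLines(c("id\tlocality\tscientificName",
               "X1\tEquus sp.\tquarry"),
             file.path(dir, "occurrence.txt"))
  writeLines(c(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">',
    ' <core rowType="http://rs.tdwg.org/dwc/terms/Occurrence" encoding="UTF-8"',
    '  fieldsTerminatedBy="\\t" linesTerminatedBy="\\n" ignoreHeaderLines="1">',
    '  <files><location>occurrence.txt</location></files>',
    '  <id index="0"/>',
    '  <field index="1" term="http://rs.tdwg.org/dwc/terms/scientificName"/>',
    '  <field index="2" term="http://rs.tdwg.org/dwc/terms/locality"/>',
    ' </core>',
    '</archive>'), file.path(dir, "meta.xml"))
  arch <- read_archive(dir)
  expect_identical(arch$occurrences$scientificName, "Equus sp.")
  expect_identical(arch$occurrences$locality, "quarry")
})

test_that("a declared field index beyond row width pads with empties and warns", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tsciName", "X1\tEquus sp."), file.path(dir, "occurrence.txt"))
  writeLines(c(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">',
    ' <core rowType="http://rs.tdwg.org/dwc/terms/Occurrence" encoding="UTF-8"',
    '  fieldsTerminatedBy="\\t" linesTerminatedBy="\\n" ignoreHeaderLines="1">',
    '  <files><location>occurrence.txt</location></files>',
    '  <id index="0"/>',
    '  <field index="1" term="http://rs.tdwg.org/dwc/terms/scientificName"/>',
    '  <field index="7" term="http://rs.tdwg.org/dwc/terms/locality"/>',
    ' </core>',
    '</archive>'), file.path(dir, "meta.xml"))
  expect_warning(arch <- read_archive(dir), "beyond row width")
  expect_identical(arch$occurrences$locality, "")
})

test_that("structural failures raise archive-format errors", {
  dir <- withr::local_tempdir()
  expect_error(read_archive(file.path(dir, "missing")),
               class = "chrono_archive_format_error")
  empty <- file.path(dir, "noMeta")
  dir.create(empty)
  expect_error(read_archive(empty), class = "chrono_archive_format_error")
  # meta.xml referencing an absent data file
  broken <- file.path(dir, "broken")
  dir.create(broken)
  writeLines(c(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">',
    ' <core rowType="http://rs.tdwg.org/dwc/terms/Occurrence">',
    '  <files><location>gone.txt</location></files><id index="0"/>',
    ' </core></archive>'), file.path(broken, "meta.xml"))
  expect_error(read_archive(broken), class = "chrono_archive_format_error")
})

test_that("undecodable bytes raise an encoding error naming file and line", {
  dir <- withr::local_tempdir()
  con <- file(file.path(dir, "occurrence.txt"), "wb")
  writeLines("id\tlocality", con)
  writeBin(c(charToRaw("X1\tbad "), as.raw(0xff), as.raw(0xfe),
             charToRaw("\n")), con)
  close(con)
  writeLines(c(
    '<archive xmlns="http://rs.tdwg.org/dwc/text/">',
    ' <core rowType="http://rs.tdwg.org/dwc/terms/Occurrence" encoding="UTF-8"',
    '  fieldsTerminatedBy="\\t" linesTerminatedBy="\\n" ignoreHeaderLines="1">',
    '  <files><location>occurrence.txt</location></files>',
    '  <id index="0"/>',
    '  <field index="1" term="http://rs.tdwg.org/dwc/terms/locality"/>',
    ' </core></archive>'), file.path(dir, "meta.xml"))
  err <- tryCatch(read_archive(dir), chrono_encoding_error = function(e) e)
  expect_s3_class(err, "chrono_encoding_error")
  expect_match(conditionMessage(err), "occurrence.txt")
  expect_match(conditionMessage(err), "line 2")
})

test_that("permuting extension rows never changes the per-core record multiset", {
  hr <- make_preset("hawk_rim")
  recs <- rbind(hr$chronometric_ages,
                chronometric_age_record(coreReference = "HR-LOC1-088",
                                        chronometricAgeID = "HR-CA-0",
                                        chronometricAgeRemarks = "third assay"))
  occ <- hr$occurrence
  read_sorted <- function(rows) {
    dir <- withr::local_tempdir()
    write_archive(occ, recs[rows, ], dir)
    sorted_records(read_archive(dir)$chronometric_ages)
  }
  base <- read_sorted(1:3)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_identical(read_sorted(perm), base)
  }
})

test_that("unrecognized extension row types are preserved opaquely", {
  dir <- withr::local_tempdir()
  fx <- make_preset("north_midden")
  write_archive(fx$occurrence, fx$chronometric_ages, dir)
  writeLines(c("coreid\tidentifiedBy", "NM-FEAT17-001\tSomeone"),
             file.path(dir, "identification.txt"))
  meta <- xml2::read_xml(file.path(dir, "meta.xml"))
  ext <- xml2::xml_add_child(
    meta, "extension",
    rowType = "http://rs.tdwg.org/dwc/terms/Identification",
    fieldsTerminatedBy = "\\t", linesTerminatedBy = "\\n",
    encoding = "UTF-8", ignoreHeaderLines = "1"
  )
  files <- xml2::xml_add_child(ext, "files")
  xml2::xml_add_child(files, "location", "identification.txt")
  xml2::xml_add_child(ext, "coreid", index = "0")
  xml2::xml_add_child(ext, "field", index = "1",
                      term = "http://rs.tdwg.org/dwc/terms/identifiedBy")
  xml2::write_xml(meta, file.path(dir, "meta.xml"))

  expect_message(arch <- read_archive(dir), "unrecognized row type")
  expect_named(arch$other_extensions,
               "http://rs.tdwg.org/dwc/terms/Identification")
  expect_identical(
    arch$other_extensions[[1]]$identifiedBy, "Someone"
  )
  expect_identical(nrow(arch$chronometric_ages), 1L)
})

test_that("zipped archives read identically to unpacked directories", {
  fx <- make_preset("baptizing_springs")
  dir <- withr::local_tempdir()
  write_archive(fx$occurrence, fx$chronometric_ages, dir)
  zipfile <- file.path(withr::local_tempdir(), "arch.zip")
  status <- system2("python", c("-m", "zipfile", "-c", shQuote(zipfile),
                                shQuote(file.path(dir, "meta.xml")),
                                shQuote(file.path(dir, "occurrence.txt")),
                                shQuote(file.path(dir, "chronometricage.txt"))))
  expect_identical(status, 0L)
  arch <- read_archive(zipfile)
  expect_identical(sorted_records(arch$chronometric_ages),
                   sorted_records(fx$chronometric_ages))
})
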