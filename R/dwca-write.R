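# Darwin Core Archive writing.  The writer dialect is fixed for
# reproducibility: UTF-8, tab-delimited, LF line endings, one header line,
# double-quote enclosure only where a value contains the delimiter, a quote
# or a line break.  The reader, by contrast, honors whatever meta.xml
# declares.

quote_dwca <- function(x) {
  need <- grepl('[\t"\n\r]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need], fixed = TRUE), '"')
  x
}

write_data_file <- function(tab, path, header) {
  lines <- c(
    paste(header, collapse = "\t"),
    if (nrow(tab)) {
      apply(as.matrix(tab), 1L, function(row) {
        paste(quote_dwca(chrono_chr(row)), collapse = "\t")
      })
    }
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

add_file_node <- function(parent, node_name, row_type, location, id_name,
                          field_terms) {
  node <- xml2::xml_add_child(
    parent, node_name,
    rowType = row_type, encoding = "UTF-8",
    fieldsTerminatedBy = "\\t", linesTerminatedBy = "\\n",
    fieldsEnclosedBy = "\"", ignoreHeaderLines = "1"
  )
  files <- xml2::xml_add_child(node, "files")
  xml2::xml_add_child(files, "location", location)
  xml2::xml_add_child(node, id_name, index = "0")
  for (i in seq_along(field_terms)) {
    xml2::xml_add_child(node, "field",
                        index = as.character(i),
                        term = field_terms[[i]])
  }
  node
}

#' Write a Darwin Core Archive with ChronometricAge extension rows
#'
#' Emits an unpacked archive directory: `meta.xml` (core row type Occurrence,
#' extension row type `http://rs.tdwg.org/chrono/terms/ChronometricAge`,
#' extension field terms fully qualified in the chrono namespace), a
#' tab-delimited UTF-8 `occurrence.txt` and, when extension records exist, a
#' `chronometricage.txt`.  Only terms carrying at least one non-empty value
#' get columns.  The coreid/id column is emitted at index 0; the
#' authoritative mapping is meta.xml's index attributes.  Extension rows are
#' sorted by (coreReference, chronometricAgeID, input order) for stable
#' diffs.  The core record's `id` is written verbatim as the coreid.
#'
#' @param occurrences Tibble of core records with a non-empty `id` column;
#'   remaining columns are Darwin Core term local names.
#' @param records ChronometricAge records (tibble); every `coreReference`
#'   must appear among `occurrences$id` unless `force = TRUE`.
#' @param dest Destination directory (created if needed).
#' @param force Write even when extension rows are orphaned.
#' @return The archive's `dwca_descriptor`, invisibly re-parsed from the
#'   written meta.xml.
#' @export
write_archive <- function(occurrences, records, dest, force = FALSE) {
  occurrences <- tibble::as_tibble(occurrences)
  if (!"id" %in% names(occurrences) || any(!nzchar(chrono_chr(occurrences$id)))) {
    chrono_abort("every core record needs a non-empty 'id'",
                 "chrono_consistency_error")
  }
  records <- as_chronometric_age_records(records)
  orphan <- setdiff(records$coreReference, occurrences$id)
  if (length(orphan) && !force) {
    chrono_abort(
      sprintf("extension row(s) reference unknown core id(s): %s",
              paste(orphan, collapse = ", ")),
      "chrono_consistency_error"
    )
  }

  dir.create(dest, recursive = TRUE, showWarnings = FALSE)

  core_cols <- setdiff(names(occurrences), "id")
  core_cols <- core_cols[vapply(core_cols, function(nm) {
    any(nzchar(chrono_chr(occurrences[[nm]])))
  }, logical(1))]
  core_tab <- occurrences[, c("id", core_cols), drop = FALSE]
  write_data_file(core_tab, file.path(dest, "occurrence.txt"),
                  c("id", core_cols))

  ext_cols <- CHRONO_PROPERTY_TERMS[vapply(CHRONO_PROPERTY_TERMS, function(nm) {
    any(nzchar(records[[nm]]))
  }, logical(1))]
  has_ext <- nrow(records) > 0L
  if (has_ext) {
    ord <- order(records$coreReference, records$chronometricAgeID,
                 method = "radix")
    ext_tab <- records[ord, c("coreReference", ext_cols), drop = FALSE]
    write_data_file(ext_tab, file.path(dest, "chronometricage.txt"),
                    c("coreid", ext_cols))
  }

  doc <- xml2::xml_new_root("archive", xmlns = DWC_TEXT_NS)
  add_file_node(doc, "core", DWC_OCCURRENCE_ROWTYPE, "occurrence.txt",
                "id", paste0(DWC_IRI_BASE, core_cols))
  if (has_ext) {
    add_file_node(doc, "extension", CHRONO_ROWTYPE, "chronometricage.txt",
                  "coreid", paste0(CHRONO_IRI_BASE, ext_cols))
  }
  xml2::write_xml(doc, file.path(dest, "meta.xml"))

  invisible(parse_meta_xml(file.path(dest, "meta.xml")))
}
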