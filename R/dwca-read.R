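# Darwin Core Archive reading: meta.xml-driven star schema with one core
# file and extension files linked by coreid.  The column->term mapping always
# follows meta.xml's index attributes, never header order.

DWC_TEXT_NS <- "http://rs.tdwg.org/dwc/text/"

# meta.xml stores control characters escaped ("\t", "\n")
unescape_meta <- function(x) {
  if (is.null(x) || is.na(x)) return(x)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x
}

parse_file_node <- function(node, is_core) {
  attr_of <- function(name, default = NA_character_) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) default else v
  }
  loc <- xml2::xml_text(xml2::xml_find_first(node, ".//files/location"))
  id_node <- xml2::xml_find_first(node, if (is_core) "./id" else "./coreid")
  id_index <- if (inherits(id_node, "xml_missing")) NA_integer_
              else as.integer(xml2::xml_attr(id_node, "index"))
  field_nodes <- xml2::xml_find_all(node, "./field")
  idx <- as.integer(xml2::xml_attr(field_nodes, "index"))
  term <- xml2::xml_attr(field_nodes, "term")
  keep <- !is.na(idx)
  fields <- stats::setNames(term[keep], as.character(idx[keep]))
  if (anyDuplicated(names(fields))) {
    chrono_abort(sprintf("meta.xml declares duplicate field indices for '%s'",
                         loc),
                 "chrono_archive_format_error")
  }
  list(
    rowType = attr_of("rowType"),
    file = loc,
    idIndex = id_index,
    fields = fields,
    fieldsTerminatedBy = unescape_meta(attr_of("fieldsTerminatedBy", "\\t")),
    linesTerminatedBy = unescape_meta(attr_of("linesTerminatedBy", "\\n")),
    fieldsEnclosedBy = {
      q <- attr_of("fieldsEnclosedBy", "")
      if (is.na(q)) "" else q
    },
    encoding = {
      e <- attr_of("encoding", "UTF-8")
      if (is.na(e) || !nzchar(e)) "UTF-8" else e
    },
    ignoreHeaderLines = {
      h <- attr_of("ignoreHeaderLines", "0")
      if (is.na(h)) 0L else as.integer(h)
    }
  )
}

parse_meta_xml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  core_nodes <- xml2::xml_find_all(doc, "./core")
  if (length(core_nodes) != 1L) {
    chrono_abort("meta.xml must declare exactly one core file",
                 "chrono_archive_format_error")
  }
  core <- parse_file_node(core_nodes[[1L]], is_core = TRUE)
  ext_nodes <- xml2::xml_find_all(doc, "./extension")
  exts <- lapply(ext_nodes, parse_file_node, is_core = FALSE)
  for (e in exts) {
    if (is.na(e$idIndex)) {
      chrono_abort(sprintf("extension '%s' declares no coreid index", e$file),
                   "chrono_archive_format_error")
    }
  }
  structure(list(core = core, extensions = exts),
            class = "dwca_descriptor")
}

#' @export
print.dwca_descriptor <- function(x, ...) {
  cat(sprintf("<Darwin Core Archive descriptor>\n  core: %s (%s)\n",
              x$core$file, x$core$rowType))
  for (e in x$extensions) {
    cat(sprintf("  extension: %s (%s)\n", e$file, e$rowType))
  }
  invisible(x)
}

# Decode one data file into a character matrix honoring the declared dialect,
# with per-line encoding validation.
read_data_file <- function(dir, fd) {
  path <- file.path(dir, fd$file)
  if (!file.exists(path)) {
    chrono_abort(sprintf("data file '%s' referenced by meta.xml is absent",
                         fd$file),
                 "chrono_archive_format_error")
  }
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  # split on physical line breaks byte-wise: regex splitting would choke on
  # the very bytes the encoding check is meant to catch
  norm <- gsub("\r\n", "\n", txt, fixed = TRUE, useBytes = TRUE)
  norm <- gsub("\r", "\n", norm, fixed = TRUE, useBytes = TRUE)
  lines_for_check <- strsplit(norm, "\n", fixed = TRUE, useBytes = TRUE)[[1L]]
  if (toupper(fd$encoding) %in% c("UTF-8", "UTF8")) {
    bad <- which(!validUTF8(lines_for_check))
    Encoding(txt) <- "UTF-8"
  } else {
    conv <- iconv(lines_for_check, from = fd$encoding, to = "UTF-8")
    bad <- which(is.na(conv) & !is.na(lines_for_check))
    txt <- iconv(txt, from = fd$encoding, to = "UTF-8")
  }
  if (length(bad)) {
    chrono_abort(
      sprintf("undecodable bytes in '%s' line %d under declared encoding %s",
              fd$file, bad[1L], fd$encoding),
      "chrono_encoding_error"
    )
  }
  if (!endsWith(txt, "\n")) txt <- paste0(txt, "\n")
  quote_char <- fd$fieldsEnclosedBy
  tab <- utils::read.table(
    text = txt, sep = fd$fieldsTerminatedBy,
    quote = if (nzchar(quote_char)) quote_char else "",
    header = FALSE, skip = fd$ignoreHeaderLines,
    colClasses = "character", fill = TRUE, comment.char = "",
    na.strings = character(0), blank.lines.skip = TRUE,
    stringsAsFactors = FALSE
  )
  as.matrix(tab)
}

# Column by meta.xml index; short rows are padded with empty values.
column_at <- function(mat, index, fd) {
  if (is.na(index)) return(rep("", nrow(mat)))
  j <- index + 1L  # meta.xml indices are zero-based
  if (j > ncol(mat)) {
    warning(sprintf(
      "meta.xml declares field index %d beyond row width in '%s'; padding with empty values",
      index, fd$file))
    return(rep("", nrow(mat)))
  }
  out <- unname(mat[, j])
  out[is.na(out)] <- ""
  out
}

decode_with_fields <- function(mat, fd, id_name) {
  out <- list()
  out[[id_name]] <- column_at(mat, fd$idIndex, fd)
  for (ix in names(fd$fields)) {
    term_iri <- fd$fields[[ix]]
    local <- basename(term_iri)
    if (local %in% names(out)) next
    out[[local]] <- column_at(mat, as.integer(ix), fd)
  }
  tibble::as_tibble(out)
}

#' Read a Darwin Core Archive
#'
#' Accepts a zip file or an unpacked archive directory containing
#' `meta.xml`.  Rows of extension files with row type
#' `http://rs.tdwg.org/chrono/terms/ChronometricAge` are decoded into
#' ChronometricAge records with `coreReference` taken from the coreid
#' column.  Extension files of other row types are preserved opaquely (as
#' raw tibbles under `other_extensions`, keyed by row type) and reported,
#' never dropped.
#'
#' @param path Path to a `.zip` archive or an unpacked archive directory.
#' @return An object of class `chrono_archive`: a list with elements
#'   `descriptor` (the parsed meta.xml), `occurrences` (tibble with column
#'   `id` plus one column per mapped Darwin Core term, named by local name),
#'   `chronometric_ages` (canonical record tibble) and `other_extensions`.
#' @section Errors:
#' `chrono_archive_format_error` if meta.xml is missing/invalid or a
#' referenced data file is absent; `chrono_encoding_error` (naming file and
#' line) on bytes undecodable under the declared encoding.
#' @export
read_archive <- function(path) {
  if (file.exists(path) && !dir.exists(path)) {
    exdir <- tempfile("dwca_")
    utils::unzip(path, exdir = exdir)
    path <- exdir
  }
  if (!dir.exists(path)) {
    chrono_abort(sprintf("archive location '%s' does not exist", path),
                 "chrono_archive_format_error")
  }
  meta <- file.path(path, "meta.xml")
  if (!file.exists(meta)) {
    # tolerate one wrapping directory inside a zip
    sub <- list.dirs(path, recursive = FALSE)
    hit <- sub[file.exists(file.path(sub, "meta.xml"))]
    if (length(hit) == 1L) {
      path <- hit
      meta <- file.path(path, "meta.xml")
    } else {
      chrono_abort("archive has no meta.xml", "chrono_archive_format_error")
    }
  }
  desc <- parse_meta_xml(meta)

  core_mat <- read_data_file(path, desc$core)
  occurrences <- decode_with_fields(core_mat, desc$core, "id")

  ages <- chronometric_age_records()
  other <- list()
  for (e in desc$extensions) {
    mat <- read_data_file(path, e)
    if (identical(e$rowType, CHRONO_ROWTYPE)) {
      raw <- decode_with_fields(mat, e, "coreReference")
      unknown <- setdiff(names(raw), c("coreReference", CHRONO_PROPERTY_TERMS))
      if (length(unknown)) {
        warning(sprintf("ignoring unrecognized ChronometricAge column(s): %s",
                        paste(unknown, collapse = ", ")))
      }
      ages <- rbind(ages, as_chronometric_age_records(raw))
    } else {
      message(sprintf("preserving extension of unrecognized row type %s (%s)",
                      e$rowType, e$file))
      other[[e$rowType]] <- decode_with_fields(mat, e, "coreid")
    }
  }

  structure(
    list(descriptor = desc, occurrences = occurrences,
         chronometric_ages = ages, other_extensions = other),
    class = "chrono_archive"
  )
}

#' @export
print.chrono_archive <- function(x, ...) {
  cat(sprintf("<chrono_archive: %d occurrences, %d ChronometricAge records, %d other extension(s)>\n",
              nrow(x$occurrences), nrow(x$chronometric_ages),
              length(x$other_extensions)))
  invisible(x)
}
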