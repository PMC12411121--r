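# Reading FAERS DRUG ASCII files and the unique-record definition.
#
# Public FAERS quarterly extracts ship "$"-delimited, unquoted, header-first
# ASCII files.  A drug record's identity -- the unit on which coverage is
# computed -- is the 7-tuple (drugname, prod_ai, route, dose_amt, dose_form,
# dose_unit, nda_num), compared byte-exact on the raw field values, with a
# missing value equal only to another missing value.

#' Seven FAERS fields defining drug-record identity
#' @export
KEY_FIELDS <- c("drugname", "prod_ai", "route", "dose_amt", "dose_form",
                "dose_unit", "nda_num")

#' Parse a FAERS-format DRUG file
#'
#' Reads a "$"-delimited (configurable), unquoted, header-first drug file.
#' Empty, whitespace-only and literal `NULL` cells parse to `NA` (the missing
#' sentinel); all other cells are kept byte-exact.  Lines whose cell count
#' does not match the header are skipped and reported with their line
#' numbers, never silently dropped.
#'
#' @param path file path.
#' @param delim field delimiter, default `"$"` (the public FAERS dialect);
#'   quoting is not interpreted.
#' @param encoding `"UTF-8"`, `"latin1"`, or `NULL` to auto-detect.
#' @return a `data.table` with columns `report_id`, `drug_seq` and the seven
#'   key fields, one row per well-formed data line.  Skipped line numbers are
#'   attached as attribute `"skipped"` (also raised as a warning).
#' @export
parse_drug_file <- function(path, delim = "$", encoding = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(encoding)) {
    if (any(!validUTF8(lines))) lines <- iconv(lines, "latin1", "UTF-8")
  } else if (encoding != "UTF-8") {
    lines <- iconv(lines, encoding, "UTF-8")
  }
  if (length(lines) == 0L) stop("empty file (no header): ", path)
  header <- tolower(trimws(strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]))
  for (f in KEY_FIELDS) {
    if (!f %in% header) stop("missing required column in header: ", f)
  }
  id_col <- intersect(c("primaryid", "isr", "report_id", "caseid"), header)[1L]
  if (is.na(id_col)) stop("missing required column in header: a report identifier ",
                          "(one of primaryid/isr/report_id/caseid)")
  seq_col <- intersect(c("drug_seq", "dsg_drug_seq"), header)[1L]
  ncol_exp <- length(header)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  cells <- strsplit(body, delim, fixed = TRUE)
  # a line ending in the delimiter loses its final empty cell in strsplit
  cells <- lapply(cells, function(x) if (length(x) == ncol_exp - 1L) c(x, "") else x)
  nc <- lengths(cells)
  bad <- which(nc != ncol_exp)
  if (length(bad)) {
    warning(sprintf("skipped %d malformed line(s) (cell count != %d) at line(s): %s",
                    length(bad), ncol_exp,
                    paste(bad + 1L, collapse = ", ")))
    cells <- cells[-bad]
  }
  grab <- function(col) {
    if (is.na(col)) return(rep(NA_character_, length(cells)))
    i <- match(col, header)
    as_field(vapply(cells, `[[`, character(1), i))
  }
  out <- data.table(
    report_id = grab(id_col),
    drug_seq = grab(seq_col)
  )
  for (f in KEY_FIELDS) out[, (f) := grab(f)]
  data.table::setattr(out, "skipped", if (length(bad)) bad + 1L else integer(0))
  out[]
}

#' Write drug records back to FAERS format
#'
#' Inverse of [parse_drug_file()] (missing values become empty cells), used
#' by the fixture generator and for round-trip checks.
#'
#' @param records a data.table as returned by [parse_drug_file()].
#' @param path output path.
#' @param delim field delimiter.
#' @export
write_drug_file <- function(records, path, delim = "$") {
  cols <- c("primaryid", "drug_seq", KEY_FIELDS)
  dt <- as.data.table(records)
  vals <- cbind(dt$report_id, dt$drug_seq,
                as.matrix(dt[, KEY_FIELDS, with = FALSE]))
  vals[is.na(vals)] <- ""
  lines <- c(paste(cols, collapse = delim),
             apply(vals, 1L, paste, collapse = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Identity key of a drug record
#'
#' Deterministic projection of the seven identity fields; report identifiers
#' are deliberately excluded (they name the report, not the drug-record
#' class).  Missing stays missing.
#'
#' @param record a one-row data.frame / named list with the seven key fields.
#' @return named character vector of length 7, class `record_key`.
#' @export
record_key <- function(record) {
  rec <- as.list(record)
  key <- vapply(KEY_FIELDS, function(f) {
    v <- rec[[f]]
    if (is.null(v) || length(v) == 0L) NA_character_ else as.character(v[[1L]])
  }, character(1))
  structure(key, class = "record_key")
}

#' Compare two record keys
#'
#' Equal iff all seven components are equal, with missing equal only to
#' missing.
#'
#' @param a,b `record_key` objects.
#' @return logical scalar.
#' @export
record_key_equal <- function(a, b) {
  identical(unname(unclass(a)), unname(unclass(b)))
}

#' Group drug records into unique records
#'
#' @param records data.table of parsed records.
#' @return data.table with the seven key fields plus `n` (multiplicity);
#'   `sum(n)` equals `nrow(records)` and keys are pairwise distinct.
#' @export
unique_records <- function(records) {
  dt <- as.data.table(records)
  if (nrow(dt) == 0L) {
    out <- dt[, KEY_FIELDS, with = FALSE]
    out[, n := integer(0)]
    return(out[])
  }
  dt[, .(n = .N), by = KEY_FIELDS]
}
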