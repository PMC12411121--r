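# Pipeline orchestration and coverage reporting.
#
# Coverage is the percentage of drug records for which a mapping was
# produced, computed both at record level (weighted by unique-key
# multiplicity) and at unique-record level; ATC coverage is always a subset
# of concept coverage because ATC resolution requires a prior concept
# mapping.

pct1 <- function(num, den) if (den == 0L) 0 else round(100 * num / den, 1)

#' Coverage statistics for a mapping run
#'
#' @param mapping mapping table as returned by [map_records()] (one row per
#'   unique record, with multiplicity column `n`).
#' @return an object of class `coverage_stats`: totals, mapped and ATC
#'   counts at record and unique-record granularity, per-step match counts,
#'   and percentages at one decimal.
#' @export
coverage_report <- function(mapping) {
  dt <- as.data.table(mapping)
  mapped <- !is.na(dt$matched_step)
  atc <- !is.na(dt$atc_code)
  per_step <- vapply(1:6, function(k) sum(dt$n[which(dt$matched_step == k)]),
                     numeric(1))
  names(per_step) <- STEP_LABELS
  out <- list(
    total_records = sum(dt$n),
    total_unique = nrow(dt),
    mapped_records = sum(dt$n[mapped]),
    mapped_unique = sum(mapped),
    atc_records = sum(dt$n[atc]),
    atc_unique = sum(atc),
    per_step_records = per_step,
    pct_mapped_records = pct1(sum(dt$n[mapped]), sum(dt$n)),
    pct_mapped_unique = pct1(sum(mapped), nrow(dt)),
    pct_atc_records = pct1(sum(dt$n[atc]), sum(dt$n)),
    pct_atc_unique = pct1(sum(atc), nrow(dt))
  )
  stopifnot(out$mapped_records <= out$total_records,
            out$atc_records <= out$mapped_records,
            out$atc_unique <= out$mapped_unique,
            sum(per_step) == out$mapped_records)
  structure(out, class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Coverage\n",
           "  records: %d total, %d (%.1f%%) mapped to drug concepts, ",
           "%d (%.1f%%) to ATC\n",
           "  unique:  %d total, %d (%.1f%%) mapped to drug concepts, ",
           "%d (%.1f%%) to ATC\n"),
    x$total_records, x$mapped_records, x$pct_mapped_records,
    x$atc_records, x$pct_atc_records,
    x$total_unique, x$mapped_unique, x$pct_mapped_unique,
    x$atc_unique, x$pct_atc_unique))
  cat("  per step:",
      paste(sprintf("%s=%d", names(x$per_step_records),
                    as.integer(x$per_step_records)), collapse = " "), "\n")
  invisible(x)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Recognised keys:
#' `input`, `vocab_dir`, `out_dir`, `delimiter`, `expand_ingredients`,
#' `seed`, `verbose`.
#'
#' @param path config file path.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  lines <- read_lexicon_lines(path)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) trimws(paste(x[-1L], collapse = "=")))
  names(out) <- vapply(kv, function(x) trimws(x[[1L]]), character(1))
  out
}

#' Run the full standardisation pipeline
#'
#' Parses a FAERS drug file, loads the vocabulary directory, maps every
#' unique record through the cascade, and writes the mapping table
#' (`mapping.tsv`), the coverage report (`coverage.tsv`) and a
#' machine-readable summary (`coverage.json`) to `out_dir`.
#'
#' @param input FAERS drug file path.
#' @param vocab_dir vocabulary directory for [load_vocab()].
#' @param out_dir output directory (created if needed).
#' @param delim input-file delimiter.
#' @param options see [map_options()].
#' @param verbose emit per-step progress messages.
#' @return invisibly, a list with `mapping` (data.table) and `stats`
#'   (`coverage_stats`).
#' @export
run_pipeline <- function(input, vocab_dir, out_dir, delim = "$",
                         options = map_options(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("loading vocabulary from ", vocab_dir)
  index <- load_vocab(vocab_dir)
  say("parsing ", input)
  records <- parse_drug_file(input, delim = delim)
  say(nrow(records), " records parsed")
  mapping <- map_records(records, index, options)
  stats <- coverage_report(mapping)
  say(sprintf("%.1f%% of records mapped to drug concepts, %.1f%% to ATC",
              stats$pct_mapped_records, stats$pct_atc_records))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(mapping, file.path(out_dir, "mapping.tsv"), sep = "\t", quote = FALSE,
         na = "")
  cov <- data.table(
    metric = c("total_records", "total_unique", "mapped_records",
               "mapped_unique", "atc_records", "atc_unique",
               "pct_mapped_records", "pct_mapped_unique",
               "pct_atc_records", "pct_atc_unique",
               paste0("step_", tolower(names(stats$per_step_records)))),
    value = c(stats$total_records, stats$total_unique, stats$mapped_records,
              stats$mapped_unique, stats$atc_records, stats$atc_unique,
              stats$pct_mapped_records, stats$pct_mapped_unique,
              stats$pct_atc_records, stats$pct_atc_unique,
              unname(stats$per_step_records)))
  fwrite(cov, file.path(out_dir, "coverage.tsv"), sep = "\t", quote = FALSE)
  jsonlite::write_json(unclass(stats), file.path(out_dir, "coverage.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(mapping = mapping, stats = stats))
}
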