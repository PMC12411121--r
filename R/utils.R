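# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Test whether field values are missing
#'
#' FAERS cells that are empty, whitespace-only, or the literal token "NULL"
#' (any case) parse to the missing sentinel `NA_character_`.  This helper is
#' the single definition of "missing" used throughout the package.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_missing <- function(x) {
  is.na(x) | !nzchar(trimws(x)) | toupper(trimws(x)) == "NULL"
}

# Map raw cells to NA under the missing rule, otherwise keep them byte-exact
# (original casing and internal whitespace are the normalizer's business).
as_field <- function(x) {
  x[is_missing(x)] <- NA_character_
  x
}

# Collapse an integer id set to its canonical serialised form.
ids_chr <- function(ids) {
  if (length(ids) == 0L) return("")
  paste(sort(unique(as.integer(ids))), collapse = ",")
}

chr_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
}

# Run an expression under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

read_lexicon_lines <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
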