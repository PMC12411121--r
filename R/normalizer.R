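# Name cleaning and canonicalisation.
#
# FAERS drugname strings carry dosage fragments, routes of administration,
# parentheticals and assorted punctuation on top of the actual drug name.
# Matching is exact (no edit-distance rescue), so the cascade of cleaning
# stages below is what gives the mapper its tolerance: each record is tried
# against the vocabulary in least-destructive-first order, from the raw
# trimmed string down to the fully stripped one.

.lexicons <- new.env(parent = emptyenv())

#' Normalizer lexicons
#'
#' Loads (and caches) the pattern/lexicon files shipped with the package:
#' dosage units, route/dose-form tokens, word-split stopwords, abbreviation
#' expansions and UK-to-US spelling variants.  All files are plain text under
#' `inst/extdata` and can be inspected or overridden via the `dir` argument.
#'
#' @param dir directory holding the lexicon files; defaults to the files
#'   shipped with the package.
#' @return a list with elements `units`, `routes`, `stopwords`, `abbrev`,
#'   `spelling`, `route_classes`, `dose_form_routes`, `dosage_pattern`.
#' @export
normalizer_lexicons <- function(dir = NULL) {
  key <- dir %||% "__default__"
  if (!is.null(.lexicons[[key]])) return(.lexicons[[key]])
  path <- function(f) {
    if (is.null(dir)) system.file("extdata", f, package = "faersmapr", mustWork = TRUE)
    else file.path(dir, f)
  }
  units <- tolower(read_lexicon_lines(path("dosage_units.txt")))
  routes <- tolower(read_lexicon_lines(path("route_tokens.txt")))
  stop_ <- tolower(read_lexicon_lines(path("stopwords.txt")))
  ab <- utils::read.delim(path("abbreviations.tsv"), stringsAsFactors = FALSE)
  sp <- utils::read.delim(path("spelling_variants.tsv"), stringsAsFactors = FALSE)
  rc <- utils::read.delim(path("route_classes.tsv"), stringsAsFactors = FALSE)
  dfr <- utils::read.delim(path("dose_form_routes.tsv"), stringsAsFactors = FALSE)
  # longest-first so e.g. "mg/ml" wins over "mg"
  u <- units[order(-nchar(units))]
  u_esc <- gsub("([][{}()+*^$|\\\\?.%])", "\\\\\\1", u)
  num <- "[0-9]+(?:[.,][0-9]+)?"
  lex <- list(
    units = units,
    routes = routes,
    stopwords = stop_,
    abbrev = setNames(tolower(ab$expansion), tolower(ab$abbrev)),
    spelling = setNames(tolower(sp$us), tolower(sp$uk)),
    route_classes = rc,
    dose_form_routes = dfr,
    dosage_pattern = sprintf("(?i)(?<![A-Za-z0-9])%s\\s*(?:%s)(?![A-Za-z0-9])",
                             num, paste(u_esc, collapse = "|"))
  )
  assign(key, lex, envir = .lexicons)
  lex
}

collapse_ws <- function(x) trimws(gsub("\\s+", " ", x))

#' Remove dosage tokens from a drug name
#'
#' Strips number-plus-unit fragments such as `500MG`, `0.5%`, `10 mg/mL`.
#' Bare numbers and alphanumeric name parts (`B12`) are retained, since the
#' pattern requires a leading number immediately followed by a known unit.
#'
#' @param name character vector.
#' @param lexicons see [normalizer_lexicons()].
#' @return character vector with dosage tokens removed and whitespace
#'   collapsed.
#' @export
strip_dosage <- function(name, lexicons = normalizer_lexicons()) {
  out <- gsub(lexicons$dosage_pattern, " ", name, perl = TRUE)
  # orphaned separators left behind by a removed fraction ("MG/5 ML" etc.)
  out <- gsub("(^|\\s)[%./]+(?=\\s|$)", " ", out, perl = TRUE)
  collapse_ws(out)
}

#' Remove route-of-administration tokens from a drug name
#'
#' Drops whole tokens found in the shipped route lexicon (ORAL, TABLET,
#' INJECTION, OPHTHALMIC, ...), case-insensitively; all other tokens are kept
#' in their original order.
#'
#' @inheritParams strip_dosage
#' @return character vector.
#' @export
strip_route <- function(name, lexicons = normalizer_lexicons()) {
  vapply(name, function(x) {
    if (is.na(x)) return(NA_character_)
    toks <- strsplit(collapse_ws(x), " ", fixed = TRUE)[[1L]]
    paste(toks[!(tolower(toks) %in% lexicons$routes)], collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Remove parentheticals/bracketed fragments wholesale, then squash special
# characters to spaces.  Characters used by dosage notation (digits, '.',
# '%', '/') survive so the dosage stage still sees them.
strip_special <- function(name) {
  out <- gsub("\\([^)]*\\)|\\[[^]]*\\]", " ", name)
  out <- gsub("[^A-Za-z0-9 %./]", " ", out)
  collapse_ws(out)
}

#' Ordered cleaning cascade for a drug name
#'
#' Produces the sequence of progressively cleaned variants tried by the
#' mapper: the whitespace-trimmed raw string, then cumulative removal of
#' trailing spaces/dots, special characters and parentheticals, dosage
#' tokens, and route tokens.  Consecutive duplicates are collapsed and empty
#' variants dropped, so the least-destructive distinct variants come first.
#'
#' @param name a single non-missing string.
#' @param lexicons see [normalizer_lexicons()].
#' @return a data.frame with columns `stage`
#'   (`RAW`, `TRIM`, `SPECIAL_CHARS`, `DOSAGE`, `ROUTE`) and `text`.
#' @export
clean_cascade <- function(name, lexicons = normalizer_lexicons()) {
  stopifnot(length(name) == 1L, !is.na(name))
  v1 <- trimws(name)
  v2 <- sub("[ .]+$", "", v1)
  v3 <- strip_special(v2)
  v4 <- strip_dosage(v3, lexicons)
  v5 <- strip_route(v4, lexicons)
  stage <- c("RAW", "TRIM", "SPECIAL_CHARS", "DOSAGE", "ROUTE")
  text <- c(v1, v2, v3, v4, v5)
  keep <- nzchar(text)
  stage <- stage[keep]; text <- text[keep]
  if (length(text) > 1L) {
    dup <- c(FALSE, text[-1L] == text[-length(text)])
    stage <- stage[!dup]; text <- text[!dup]
  }
  data.frame(stage = stage, text = text, stringsAsFactors = FALSE)
}

#' Canonical form of a drug name
#'
#' The canonical form is what all vocabulary name indexes are keyed on:
#' lowercase, diacritics folded to ASCII, punctuation collapsed to spaces,
#' known abbreviations expanded (`hcl` to `hydrochloride`), UK spellings
#' unified to US (`sulphasalazine` to `sulfasalazine`), and tokens sorted
#' lexicographically.  Token sorting makes the form invariant under word
#' order, so "Acetaminophen 500 MG Oral Tablet" and "oral tablet
#' acetaminophen 500 mg" canonicalise identically.  The function is
#' idempotent.
#'
#' @param name character vector; `NA` propagates.
#' @param lexicons see [normalizer_lexicons()].
#' @return character vector of canonical forms.
#' @export
canonical_form <- function(name, lexicons = normalizer_lexicons()) {
  out <- tolower(as.character(name))
  # fold common diacritics one-to-one; iconv TRANSLIT alone is
  # locale-dependent and may insert quote marks
  out <- chartr("áàâäãåéèêëíìîïóòôöõúùûüýÿñç",
                "aaaaaaeeeeiiiiooooouuuuyync", out)
  out <- iconv(out, from = "UTF-8", to = "ASCII", sub = " ")
  out <- gsub("[^a-z0-9]+", " ", out)
  out <- collapse_ws(out)
  ab <- lexicons$abbrev
  sp <- lexicons$spelling
  vapply(strsplit(out, " ", fixed = TRUE), function(toks) {
    if (length(toks) == 1L && is.na(toks)) return(NA_character_)
    m <- match(toks, names(ab)); hit <- !is.na(m)
    toks[hit] <- unname(ab[m[hit]])
    m <- match(toks, names(sp)); hit <- !is.na(m)
    toks[hit] <- unname(sp[m[hit]])
    paste(sort(toks), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify a FAERS route string into a route class
#'
#' @param route character vector of raw route field values.
#' @param lexicons see [normalizer_lexicons()].
#' @return character vector over `ORAL`, `OPHTHALMIC`, `TOPICAL`,
#'   `PARENTERAL`, `INHALATION`, `RECTAL`, `NASAL`, `VAGINAL`, `OTHER`,
#'   `UNKNOWN` (missing or unrecognized).
#' @export
classify_route <- function(route, lexicons = normalizer_lexicons()) {
  rc <- lexicons$route_classes
  key <- canonical_form(rc$route_term, lexicons)
  m <- match(canonical_form(route, lexicons), key)
  out <- rc$route_class[m]
  out[is.na(out) | is_missing(route)] <- "UNKNOWN"
  out
}

# Route class implied by a route-specific dose form, else NA.
route_from_dose_form <- function(dose_form, lexicons = normalizer_lexicons()) {
  dfr <- lexicons$dose_form_routes
  m <- match(canonical_form(dose_form, lexicons), canonical_form(dfr$dose_form, lexicons))
  dfr$route_class[m]
}
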