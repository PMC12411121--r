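# Offline vocabulary resources: concept / synonym / relationship / strength
# tables plus the brand registry, NDA table, custom mapping list and the
# RxNorm-to-ATC crosswalk.  Everything is indexed once at load time into
# hashed environments keyed on the normalizer's canonical form, so lookups
# during mapping are O(1) and read-only.

TERM_TYPES <- c("INGREDIENT", "MULTI_INGREDIENT", "BRAND_NAME",
                "CLINICAL_DRUG", "CLINICAL_DRUG_FORM", "DOSE_FORM")
VOCABS <- c("STANDARD_DRUG", "DRUG_EXTENSION", "ATC")
REL_KINDS <- c("HAS_INGREDIENT", "HAS_BRANDED_INGREDIENT", "HAS_DOSE_FORM",
               "MAPS_TO", "CONSISTS_OF")
ATC5_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"
ROUTE_CLASSES <- c("ORAL", "OPHTHALMIC", "TOPICAL", "PARENTERAL",
                   "INHALATION", "RECTAL", "NASAL", "VAGINAL", "OTHER",
                   "UNKNOWN")

# mass units convertible to mg
MASS_TO_MG <- c(mg = 1, g = 1000, gm = 1000, mcg = 0.001, ug = 0.001, kg = 1e6)

#' Normalize an NDA application number
#'
#' Strips non-digit characters and leading zeros, so `"020702"`, `"NDA
#' 20702"` and `"20702"` all normalize identically.  Returns `NA` when no
#' digits remain.
#'
#' @param x character vector.
#' @return character vector of digit strings.
#' @export
normalize_nda <- function(x) {
  out <- gsub("[^0-9]", "", as.character(x))
  out <- sub("^0+", "", out)
  out[is.na(x) | !nzchar(out)] <- NA_character_
  out
}

env_append <- function(env, key, value) {
  cur <- env[[key]]
  env[[key]] <- if (is.null(cur)) value else rbind(cur, value)
}

#' Load and index an offline drug vocabulary directory
#'
#' Reads the delimited tables (tab-separated by default) named below from
#' `dir`, validates referential integrity, and builds the read-only lookup
#' structure used by the mapper.  Required: `concept.tsv`.  Optional (treated
#' as empty when absent): `synonym.tsv`, `relationship.tsv`, `strength.tsv`,
#' `brand_registry.tsv`, `nda.tsv`, `custom_mappings.tsv`,
#' `atc_crosswalk.tsv`.
#'
#' Column schemas:
#' \itemize{
#'   \item concept: `concept_id, concept_name, vocabulary, term_type,
#'     standard[, concept_code]`
#'   \item synonym: `concept_id, synonym`
#'   \item relationship: `source_id, target_id, kind`
#'   \item strength: `drug_concept_id, ingredient_concept_id, amount, unit`
#'   \item brand_registry: `brand, ingredient_name`
#'   \item nda: `nda_num, ingredient_name`
#'   \item custom_mappings: `verbatim_name, concept_id`
#'   \item atc_crosswalk: `ingredient_concept_id, atc_code, route_class,
#'     strength_min, strength_max, strength_unit`
#' }
#'
#' @param dir directory containing the tables.
#' @param delim field delimiter of the tables, default tab.
#' @param lexicons normalizer lexicons used to canonicalise indexed names.
#' @return an object of class `vocab_index`.
#' @export
load_vocab <- function(dir, delim = "\t", lexicons = normalizer_lexicons()) {
  rd <- function(f, required = FALSE, cols = NULL) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (required) stop("missing required vocabulary table: ", f)
      return(NULL)
    }
    dt <- fread(p, sep = delim, header = TRUE, colClasses = "character",
                quote = "", na.strings = NULL, showProgress = FALSE)
    if (!is.null(cols)) {
      miss <- setdiff(cols, names(dt))
      if (length(miss)) stop(f, ": missing column(s): ", paste(miss, collapse = ", "))
    }
    dt
  }
  con <- rd("concept.tsv", required = TRUE,
            cols = c("concept_id", "concept_name", "vocabulary", "term_type", "standard"))
  con[, concept_id := as.integer(concept_id)]
  con[, standard := toupper(standard) %in% c("TRUE", "T", "Y", "YES", "1")]
  if (!"concept_code" %in% names(con)) con[, concept_code := NA_character_]
  con[, concept_code := as_field(concept_code)]
  if (anyDuplicated(con$concept_id))
    stop("duplicate concept_id in concept table: ",
         paste(unique(con$concept_id[duplicated(con$concept_id)]), collapse = ", "))
  bad <- setdiff(unique(con$vocabulary), VOCABS)
  if (length(bad)) stop("unknown vocabulary value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(con$term_type[con$vocabulary != "ATC"]), TERM_TYPES)
  if (length(bad)) stop("unknown term_type value(s): ", paste(bad, collapse = ", "))
  atc_bad <- con[vocabulary == "ATC" & !grepl(ATC5_PATTERN, concept_code)]
  if (nrow(atc_bad))
    stop("ATC concept(s) without a valid level-5 concept_code: ",
         paste(atc_bad$concept_id, collapse = ", "))

  known <- con$concept_id
  check_refs <- function(ids, table, col) {
    bad <- setdiff(unique(as.integer(ids)), known)
    if (length(bad))
      stop(table, ": ", col, " references unknown concept_id(s): ",
           paste(bad, collapse = ", "))
  }

  syn <- rd("synonym.tsv", cols = c("concept_id", "synonym"))
  if (is.null(syn)) syn <- data.table(concept_id = integer(0), synonym = character(0))
  syn[, concept_id := as.integer(concept_id)]
  if (nrow(syn)) check_refs(syn$concept_id, "synonym", "concept_id")

  rel <- rd("relationship.tsv", cols = c("source_id", "target_id", "kind"))
  if (is.null(rel)) rel <- data.table(source_id = integer(0), target_id = integer(0),
                                      kind = character(0))
  rel[, `:=`(source_id = as.integer(source_id), target_id = as.integer(target_id))]
  if (nrow(rel)) {
    check_refs(rel$source_id, "relationship", "source_id")
    check_refs(rel$target_id, "relationship", "target_id")
    bad <- setdiff(unique(rel$kind), REL_KINDS)
    if (length(bad)) stop("unknown relationship kind(s): ", paste(bad, collapse = ", "))
  }

  str_ <- rd("strength.tsv", cols = c("drug_concept_id", "ingredient_concept_id",
                                      "amount", "unit"))
  if (is.null(str_)) str_ <- data.table(drug_concept_id = integer(0),
                                        ingredient_concept_id = integer(0),
                                        amount = numeric(0), unit = character(0))
  str_[, `:=`(drug_concept_id = as.integer(drug_concept_id),
              ingredient_concept_id = as.integer(ingredient_concept_id),
              amount = as.numeric(amount))]
  if (nrow(str_)) {
    check_refs(str_$drug_concept_id, "strength", "drug_concept_id")
    check_refs(str_$ingredient_concept_id, "strength", "ingredient_concept_id")
    if (any(!is.na(str_$amount) & str_$amount <= 0))
      stop("strength: amount must be positive")
  }

  reg <- rd("brand_registry.tsv", cols = c("brand", "ingredient_name"))
  if (is.null(reg)) reg <- data.table(brand = character(0), ingredient_name = character(0))
  if (nrow(reg) && any(is_missing(reg$ingredient_name)))
    stop("brand_registry: empty ingredient_name")

  nda <- rd("nda.tsv", cols = c("nda_num", "ingredient_name"))
  if (is.null(nda)) nda <- data.table(nda_num = character(0), ingredient_name = character(0))

  cus <- rd("custom_mappings.tsv", cols = c("verbatim_name", "concept_id"))
  if (is.null(cus)) cus <- data.table(verbatim_name = character(0), concept_id = integer(0))
  cus[, concept_id := as.integer(concept_id)]
  if (nrow(cus)) {
    check_refs(cus$concept_id, "custom_mappings", "concept_id")
    if (anyDuplicated(tolower(trimws(cus$verbatim_name))))
      stop("custom_mappings: duplicate verbatim_name")
  }

  cw <- rd("atc_crosswalk.tsv", cols = c("ingredient_concept_id", "atc_code",
                                         "route_class", "strength_min",
                                         "strength_max", "strength_unit"))
  if (is.null(cw)) cw <- data.table(ingredient_concept_id = integer(0),
                                    atc_code = character(0), route_class = character(0),
                                    strength_min = numeric(0), strength_max = numeric(0),
                                    strength_unit = character(0))
  cw[, `:=`(ingredient_concept_id = as.integer(ingredient_concept_id),
            strength_min = suppressWarnings(as.numeric(strength_min)),
            strength_max = suppressWarnings(as.numeric(strength_max)),
            strength_unit = as_field(strength_unit))]
  if (nrow(cw)) {
    check_refs(cw$ingredient_concept_id, "atc_crosswalk", "ingredient_concept_id")
    bad <- cw[!grepl(ATC5_PATTERN, atc_code)]
    if (nrow(bad)) stop("atc_crosswalk: invalid ATC level-5 code(s): ",
                        paste(bad$atc_code, collapse = ", "))
    bad <- setdiff(unique(cw$route_class), c(ROUTE_CLASSES, "ANY"))
    if (length(bad)) stop("atc_crosswalk: unknown route_class: ", paste(bad, collapse = ", "))
    if (any(!is.na(cw$strength_min) & !is.na(cw$strength_max) &
            cw$strength_min > cw$strength_max))
      stop("atc_crosswalk: strength_min > strength_max")
  }

  # ---- indexes ------------------------------------------------------------
  setkey(con, concept_id)
  drug_con <- con[vocabulary != "ATC"]

  name_env <- new.env(parent = emptyenv(), hash = TRUE)
  add_names <- function(ids, texts, source) {
    canon <- canonical_form(texts, lexicons)
    for (i in seq_along(ids)) {
      if (!nzchar(canon[i]) || is.na(canon[i])) next
      env_append(name_env, canon[i],
                 data.frame(concept_id = ids[i], source = source, stringsAsFactors = FALSE))
    }
  }
  add_names(drug_con$concept_id, drug_con$concept_name, "preferred")
  if (nrow(syn)) add_names(syn$concept_id, syn$synonym, "synonym")
  # deterministic, input-order-independent contents
  for (k in ls(name_env)) {
    v <- unique(name_env[[k]])
    name_env[[k]] <- v[order(v$concept_id, v$source), , drop = FALSE]
  }

  brand_env <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(reg)) {
    canon <- canonical_form(reg$brand, lexicons)
    for (i in order(reg$ingredient_name)) {
      if (is.null(brand_env[[canon[i]]])) brand_env[[canon[i]]] <- reg$ingredient_name[i]
    }
  }

  nda_env <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(nda)) {
    key <- normalize_nda(nda$nda_num)
    for (i in order(nda$ingredient_name)) {
      if (!is.na(key[i]) && is.null(nda_env[[key[i]]]))
        nda_env[[key[i]]] <- nda$ingredient_name[i]
    }
  }

  custom_env <- new.env(parent = emptyenv(), hash = TRUE)
  if (nrow(cus)) {
    key <- tolower(trimws(cus$verbatim_name))
    for (i in seq_len(nrow(cus))) custom_env[[key[i]]] <- cus$concept_id[i]
  }

  # priority score per concept: lower is better.  standard first, then
  # STANDARD_DRUG over DRUG_EXTENSION, then ingredient-leaning term types,
  # then lowest concept_id.
  vr <- match(con$vocabulary, VOCABS)
  tr <- match(con$term_type, TERM_TYPES)
  tr[is.na(tr)] <- length(TERM_TYPES) + 1L
  score <- (!con$standard) * 1e12 + vr * 1e10 + tr * 1e8 + con$concept_id
  priority <- setNames(score, as.character(con$concept_id))

  rel_by_source <- if (nrow(rel)) split(rel, by = "source_id", keep.by = TRUE) else list()
  strength_by_drug <- if (nrow(str_)) split(str_, by = "drug_concept_id", keep.by = TRUE) else list()
  cw_by_ing <- if (nrow(cw)) split(cw, by = "ingredient_concept_id", keep.by = TRUE) else list()

  # multi-ingredient concept per exact ingredient set (lowest id wins)
  multi_ids <- con[term_type == "MULTI_INGREDIENT", concept_id]
  multi_for_set <- new.env(parent = emptyenv(), hash = TRUE)
  for (m in sort(multi_ids)) {
    rr <- rel_by_source[[as.character(m)]]
    if (is.null(rr)) next
    ings <- rr[kind %in% c("HAS_INGREDIENT", "CONSISTS_OF"), target_id]
    if (length(ings) == 0L) next
    k <- ids_chr(ings)
    if (is.null(multi_for_set[[k]])) multi_for_set[[k]] <- m
  }

  dose_form_env <- new.env(parent = emptyenv(), hash = TRUE)
  dfc <- con[term_type == "DOSE_FORM"]
  if (nrow(dfc)) {
    canon <- canonical_form(dfc$concept_name, lexicons)
    for (i in order(dfc$concept_id)) {
      if (is.null(dose_form_env[[canon[i]]])) dose_form_env[[canon[i]]] <- dfc$concept_id[i]
    }
  }

  idx <- list(
    concepts = con, synonyms = syn, relationships = rel, strengths = str_,
    brand_registry = reg, nda = nda, custom = cus, crosswalk = cw,
    name_env = name_env, brand_env = brand_env, nda_env = nda_env,
    custom_env = custom_env, dose_form_env = dose_form_env,
    rel_by_source = rel_by_source, strength_by_drug = strength_by_drug,
    cw_by_ing = cw_by_ing, multi_for_set = multi_for_set,
    priority = priority, lexicons = lexicons,
    rollup_memo = new.env(parent = emptyenv(), hash = TRUE)
  )
  class(idx) <- "vocab_index"
  idx
}

#' @export
print.vocab_index <- function(x, ...) {
  cat("<vocab_index>",
      nrow(x$concepts), "concepts;",
      nrow(x$synonyms), "synonyms;",
      nrow(x$relationships), "relationships;",
      nrow(x$brand_registry), "registry brands;",
      nrow(x$nda), "NDA entries;",
      nrow(x$custom), "custom mappings;",
      nrow(x$crosswalk), "ATC crosswalk rows\n")
  invisible(x)
}

concept_rows <- function(index, ids) {
  if (length(ids) == 0L) return(index$concepts[0L])
  index$concepts[J(sort(unique(as.integer(ids))))]
}

# canonical-form name lookup returning concept ids (optionally preferred
# terms only)
lookup_ids <- function(index, name, synonyms = TRUE) {
  canon <- canonical_form(name, index$lexicons)
  if (is.na(canon) || !nzchar(canon)) return(integer(0))
  hits <- index$name_env[[canon]]
  if (is.null(hits)) return(integer(0))
  if (!synonyms) hits <- hits[hits$source == "preferred", , drop = FALSE]
  unique(hits$concept_id)
}

#' Exact name lookup over preferred terms and synonyms
#'
#' Returns the concepts whose preferred term or any synonym equals the
#' canonical form of `name`; case, word order, diacritics, punctuation,
#' known abbreviations and UK/US spelling differences are neutralised by the
#' canonicalisation.  No fuzzy matching: a misspelling such as `cardiazem`
#' (for `cardizem`) finds nothing.
#'
#' @param index a `vocab_index`.
#' @param name a single string.
#' @param synonyms include synonym matches (default) or preferred terms only.
#' @return a `data.table` of concept rows (possibly empty).
#' @export
lookup_exact <- function(index, name, synonyms = TRUE) {
  concept_rows(index, lookup_ids(index, name, synonyms))
}

#' Resolve a brand name through the brand registry
#'
#' Canonical-form lookup in the Article-57-like brand-to-ingredient registry.
#'
#' @param index a `vocab_index`.
#' @param name brand string.
#' @return the registered ingredient name, or `NA_character_`.
#' @export
brand_to_ingredient <- function(index, name) {
  canon <- canonical_form(name, index$lexicons)
  if (is.na(canon) || !nzchar(canon)) return(NA_character_)
  index$brand_env[[canon]] %||% NA_character_
}

#' Resolve an NDA number to its active ingredient
#'
#' Matches after digit normalization (non-digits and leading zeros
#' stripped), so `"020702"` finds an entry stored as `"20702"`.
#'
#' @param index a `vocab_index`.
#' @param nda_num application-number string (may be `NA`).
#' @return the ingredient name, or `NA_character_`.
#' @export
nda_lookup <- function(index, nda_num) {
  key <- normalize_nda(nda_num)
  if (is.na(key)) return(NA_character_)
  index$nda_env[[key]] %||% NA_character_
}

# order candidate ids best-first under the vocabulary tie-break
order_by_priority <- function(index, ids) {
  if (length(ids) <= 1L) return(as.integer(ids))
  as.integer(ids[order(index$priority[as.character(ids)])])
}
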