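# ATC resolution.
#
# A single active ingredient can hold several level-5 ATC codes depending on
# therapeutic use -- typically split by route of administration (oral
# timolol C07AA06 vs ophthalmic S01ED01) or by strength (low-dose
# finasteride D11AX10 vs high-dose G04CB01).  The record's route, dose
# amount, dose form and dose unit are therefore parsed into evidence, the
# crosswalk candidates for the mapped ingredient(s) are filtered by that
# evidence, and a code is assigned only when exactly one candidate survives.
# Zero candidates or an unresolved ambiguity both yield abstention.

STRENGTH_REL_TOL <- 0.01  # +/-1% on mg-converted amounts, absorbs unit rounding

parse_strength <- function(dose_amt, dose_unit) {
  if (is_missing(dose_amt)) return(NULL)
  amt <- suppressWarnings(as.numeric(gsub(",", ".", trimws(dose_amt))))
  if (is.na(amt)) return(NULL)
  unit <- if (is_missing(dose_unit)) NA_character_ else tolower(trimws(dose_unit))
  mg <- if (!is.na(unit) && unit %in% names(MASS_TO_MG)) amt * MASS_TO_MG[[unit]] else NA_real_
  list(amount = amt, unit = unit, amount_mg = mg)
}

to_mg <- function(amount, unit) {
  unit <- tolower(unit)
  ifelse(!is.na(amount) & unit %in% names(MASS_TO_MG),
         amount * unname(MASS_TO_MG[unit]), NA_real_)
}

derive_components_impl <- function(rec, rolled_ids, raw_ids, index, notes_env = NULL) {
  lex <- index$lexicons
  nt <- function(...) if (!is.null(notes_env)) note(notes_env, "components", ...)

  ingredients <- ingredient_level(rolled_ids, index)

  strength <- parse_strength(rec$dose_amt, rec$dose_unit)
  if (is.null(strength) && !is_missing(rec$dose_amt))
    nt("dose_amt '", rec$dose_amt, "' is not numeric; strength ignored")

  dose_form_id <- NA_integer_
  if (!is_missing(rec$dose_form)) {
    hit <- index$dose_form_env[[canonical_form(rec$dose_form, lex)]]
    if (!is.null(hit)) dose_form_id <- hit
  }

  route_class <- classify_route(rec$route, lex)
  if (route_class == "UNKNOWN" && !is_missing(rec$dose_form)) {
    inferred <- route_from_dose_form(rec$dose_form, lex)
    if (!is.na(inferred)) {
      route_class <- inferred
      nt("route class ", inferred, " inferred from dose form '", rec$dose_form, "'")
    }
  }

  brand_id <- NA_integer_
  if (length(raw_ids)) {
    tts <- concept_rows(index, raw_ids)
    b <- tts[term_type == "BRAND_NAME", concept_id]
    if (length(b)) brand_id <- b[[1L]]
  }

  structure(list(
    ingredients = ingredients,
    strength = strength,
    dose_form = dose_form_id,
    brand = brand_id,
    route_class = route_class
  ), class = "drug_components")
}

#' Derive drug components from a record and its mapping
#'
#' Extracts the four pieces of evidence used for ATC resolution: the
#' ingredient set (from the rolled-up mapping, multiples expanded), the
#' strength parsed from `dose_amt` + `dose_unit` (mass units normalized to
#' mg), the dose-form concept matched from `dose_form`, and the route class
#' from `route`.  When `route` is missing but the dose form is
#' route-specific (e.g. an ophthalmic solution), the route class is inferred
#' from the form and flagged in the result.  Unparseable evidence yields
#' `NULL`/`UNKNOWN`, never an error.
#'
#' @param record one-row data.frame / named list with the seven key fields.
#' @param mapping a `mapping_result` from [map_record()]; must not be
#'   `UNMAPPED`.
#' @param index a `vocab_index`.
#' @return an object of class `drug_components` with elements `ingredients`,
#'   `strength`, `dose_form`, `brand`, `route_class`.
#' @export
derive_components <- function(record, mapping, index) {
  stopifnot(inherits(mapping, "mapping_result"))
  if (is.na(mapping$matched_step))
    stop("derive_components: mapping is UNMAPPED")
  derive_components_impl(as.list(record), mapping$rolled_concepts,
                         mapping$raw_concepts, index)
}

#' Refine components to the most detailed drug-level concept
#'
#' When the evidence supports it, returns the `CLINICAL_DRUG` concept whose
#' ingredient and strength match the components (strength compared after mg
#' conversion, within a small relative tolerance), else a
#' `CLINICAL_DRUG_FORM` matching ingredients and dose form, else `NULL`
#' (resolution proceeds at ingredient level).
#'
#' @param components a `drug_components`.
#' @param index a `vocab_index`.
#' @return a one-row concept `data.table`, or `NULL`.
#' @export
refine_to_clinical_drug <- function(components, index) {
  ings <- components$ingredients
  if (length(ings) == 0L) return(NULL)
  # clinical drug: ingredient set + strength
  st <- components$strength
  if (!is.null(st) && !is.na(st$amount_mg) && length(index$strength_by_drug)) {
    cand <- integer(0)
    for (drug_key in names(index$strength_by_drug)) {
      rows <- index$strength_by_drug[[drug_key]]
      drug_id <- as.integer(drug_key)
      row <- index$concepts[J(drug_id)]
      if (row$term_type != "CLINICAL_DRUG") next
      if (!identical(sort(unique(rows$ingredient_concept_id)), ings)) next
      mg <- to_mg(rows$amount, rows$unit)
      ok <- !is.na(mg) & abs(mg - st$amount_mg) <= STRENGTH_REL_TOL * pmax(mg, st$amount_mg)
      if (all(ok)) cand <- c(cand, drug_id)
    }
    if (length(cand)) return(index$concepts[J(min(cand))])
  }
  # clinical drug form: ingredient set + dose form
  if (!is.na(components$dose_form)) {
    cdf <- index$concepts[term_type == "CLINICAL_DRUG_FORM", concept_id]
    cand <- integer(0)
    for (f in cdf) {
      if (!(components$dose_form %in% rel_targets(index, f, "HAS_DOSE_FORM"))) next
      f_ings <- sort(unique(rel_targets(index, f, c("HAS_INGREDIENT", "CONSISTS_OF"))))
      if (identical(f_ings, ings)) cand <- c(cand, f)
    }
    if (length(cand)) return(index$concepts[J(min(cand))])
  }
  NULL
}

#' Resolve a single ATC code or abstain
#'
#' Crosswalk candidates are the entries keyed by the record's rolled-up
#' concept id(s) -- the single ingredient id, or the multiple-ingredients
#' concept id for combination products (combinations therefore resolve only
#' when the crosswalk carries an explicit combination entry).  Candidates
#' are filtered by route class (entry `ANY` always survives; an unknown
#' record route filters nothing) and by strength range when the entry
#' constrains strength and the evidence is comparable.  Exactly one
#' surviving candidate yields its code; zero or several yield abstention
#' (`NA`).
#'
#' @param components a `drug_components`.
#' @param refined optional refined drug-level concept from
#'   [refine_to_clinical_drug()] (recorded in the audit trail; candidates are
#'   ingredient-keyed).
#' @param index a `vocab_index` carrying the crosswalk.
#' @param key_ids rolled-up concept ids keying the crosswalk lookup; defaults
#'   to the single-ingredient set in `components`.
#' @param notes_env internal audit-trail accumulator.
#' @return an ATC level-5 code string, or `NA_character_`.
#' @export
resolve_atc <- function(components, refined = NULL, index, key_ids = NULL,
                        notes_env = NULL) {
  nt <- function(...) if (!is.null(notes_env)) note(notes_env, "atc", ...)
  if (is.null(key_ids)) {
    if (length(components$ingredients) != 1L) {
      nt("no combination concept key for a multi-ingredient record; abstain")
      return(NA_character_)
    }
    key_ids <- components$ingredients
  }
  cand <- rbindlist(lapply(as.character(key_ids), function(k) index$cw_by_ing[[k]]))
  if (is.null(cand) || nrow(cand) == 0L) {
    nt("no crosswalk entry for concept(s) ", ids_chr(key_ids), "; abstain")
    return(NA_character_)
  }
  # route filter
  if (components$route_class != "UNKNOWN") {
    cand <- cand[route_class == "ANY" | route_class == components$route_class]
  }
  # strength filter
  st <- components$strength
  if (!is.null(st) && !is.na(st$amount_mg) && nrow(cand)) {
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      lo <- cand$strength_min[i]; hi <- cand$strength_max[i]
      un <- cand$strength_unit[i]
      if (is.na(lo) && is.na(hi)) return(TRUE)          # unconstrained
      if (is.na(un) || !(tolower(un) %in% names(MASS_TO_MG))) return(TRUE)
      lo_mg <- if (is.na(lo)) -Inf else to_mg(lo, un) * (1 - STRENGTH_REL_TOL)
      hi_mg <- if (is.na(hi)) Inf else to_mg(hi, un) * (1 + STRENGTH_REL_TOL)
      st$amount_mg >= lo_mg && st$amount_mg <= hi_mg
    }, logical(1))
    cand <- cand[keep]
  }
  codes <- unique(cand$atc_code)
  if (length(codes) == 1L) {
    nt("resolved ", codes)
    return(codes)
  }
  nt(if (length(codes) == 0L) "no candidate survived filtering; abstain"
     else paste0(length(codes), " candidates survived filtering; abstain"))
  NA_character_
}
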