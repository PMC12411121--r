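# Roll-up: convert a matched concept of any term type to the final
# ingredient-level representation -- a single ingredient or a
# multiple-ingredients concept.  Dose forms deliberately roll up to nothing
# (a dose form names a form, not a drug), and brand names must terminate at
# ingredients, never at clinical drug forms.

ROLLUP_DEPTH_CAP <- 3L

rel_targets <- function(index, id, kinds) {
  rr <- index$rel_by_source[[as.character(id)]]
  if (is.null(rr)) return(integer(0))
  rr$target_id[rr$kind %in% kinds]
}

#' Roll a concept up to ingredient level
#'
#' Returns the set of concept ids representing `concept_id` at ingredient
#' level; every returned concept has term type `INGREDIENT` or
#' `MULTI_INGREDIENT`.
#'
#' \itemize{
#'   \item `INGREDIENT` / `MULTI_INGREDIENT`: fixed points.
#'   \item `BRAND_NAME`: follows `HAS_INGREDIENT` / `HAS_BRANDED_INGREDIENT`
#'     relations; when no direct ingredient relation exists, traverses
#'     `MAPS_TO` relations to branded drug products (depth-capped) and rolls
#'     those up instead.
#'   \item `CLINICAL_DRUG` / `CLINICAL_DRUG_FORM`: follows `HAS_INGREDIENT`
#'     relations; a single ingredient is returned directly, several resolve
#'     to the `MULTI_INGREDIENT` concept with exactly that ingredient set if
#'     one exists (lowest id on ties), else to the ingredient set itself.
#'   \item `DOSE_FORM`: the empty set.
#' }
#'
#' Results are memoised per index.  A relationship cycle raises an error
#' naming the cycle.
#'
#' @param concept_id integer id of a loaded concept.
#' @param index a `vocab_index`.
#' @return integer vector of concept ids (sorted; possibly empty).
#' @export
roll_up <- function(concept_id, index) {
  concept_id <- as.integer(concept_id)
  memo_key <- as.character(concept_id)
  hit <- index$rollup_memo[[memo_key]]
  if (!is.null(hit)) return(hit)
  out <- roll_up_impl(concept_id, index, visiting = integer(0), depth = 0L)
  index$rollup_memo[[memo_key]] <- out
  out
}

roll_up_impl <- function(id, index, visiting, depth) {
  if (id %in% visiting)
    stop("relationship cycle detected during roll-up: ",
         paste(c(visiting, id), collapse = " -> "))
  row <- index$concepts[J(id)]
  if (nrow(row) == 0L || is.na(row$concept_name))
    stop("roll_up: unknown concept_id ", id)
  tt <- row$term_type
  if (tt %in% c("INGREDIENT", "MULTI_INGREDIENT")) return(id)
  if (tt == "DOSE_FORM") return(integer(0))
  visiting <- c(visiting, id)
  ings <- integer(0)
  if (tt == "BRAND_NAME") {
    direct <- rel_targets(index, id, c("HAS_INGREDIENT", "HAS_BRANDED_INGREDIENT"))
    if (length(direct)) {
      for (t in direct) ings <- c(ings, roll_up_impl(t, index, visiting, depth + 1L))
    } else if (depth < ROLLUP_DEPTH_CAP) {
      # no direct ingredient link: go through the branded drug products
      for (t in rel_targets(index, id, "MAPS_TO"))
        ings <- c(ings, roll_up_impl(t, index, visiting, depth + 1L))
    }
  } else if (tt %in% c("CLINICAL_DRUG", "CLINICAL_DRUG_FORM")) {
    for (t in rel_targets(index, id, c("HAS_INGREDIENT", "CONSISTS_OF")))
      ings <- c(ings, roll_up_impl(t, index, visiting, depth + 1L))
  } else {
    stop("roll_up: unsupported term_type ", tt)
  }
  ings <- sort(unique(ings))
  # a traversal may surface a MULTI_INGREDIENT concept directly; expand it to
  # its members before deciding single vs multiple
  if (length(ings)) {
    tts <- concept_rows(index, ings)$term_type
    if (any(tts == "MULTI_INGREDIENT")) {
      multis <- ings[tts == "MULTI_INGREDIENT"]
      singles <- ings[tts != "MULTI_INGREDIENT"]
      if (length(singles) == 0L && length(multis) == 1L) return(multis)
      for (m in multis)
        singles <- c(singles, rel_targets(index, m, c("HAS_INGREDIENT", "CONSISTS_OF")))
      ings <- sort(unique(singles))
    }
  }
  if (length(ings) <= 1L) return(ings)
  multi <- index$multi_for_set[[ids_chr(ings)]]
  if (!is.null(multi)) return(as.integer(multi))
  ings
}

#' Expand a multiple-ingredients concept into its single ingredients
#'
#' @param concept_id id of an `INGREDIENT` (returned unchanged) or
#'   `MULTI_INGREDIENT` concept.
#' @param index a `vocab_index`.
#' @return sorted integer vector of `INGREDIENT` concept ids.
#' @export
expand_ingredients <- function(concept_id, index) {
  cid <- as.integer(concept_id)
  row <- index$concepts[J(cid)]
  if (nrow(row) == 0L || is.na(row$concept_name))
    stop("expand_ingredients: unknown concept_id ", cid)
  if (row$term_type == "INGREDIENT") return(cid)
  if (row$term_type != "MULTI_INGREDIENT")
    stop("expand_ingredients: concept ", cid, " has term_type ",
         row$term_type, ", expected INGREDIENT or MULTI_INGREDIENT")
  ings <- sort(unique(rel_targets(index, cid, c("HAS_INGREDIENT", "CONSISTS_OF"))))
  if (length(ings) < 2L)
    stop("expand_ingredients: MULTI_INGREDIENT concept ", cid,
         " has fewer than 2 ingredient relations")
  ings
}

# ingredient-level id set for a set of rolled-up ids (multis expanded)
ingredient_level <- function(ids, index) {
  if (length(ids) == 0L) return(integer(0))
  out <- integer(0)
  for (id in ids) out <- c(out, expand_ingredients(id, index))
  sort(unique(out))
}
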