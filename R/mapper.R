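# The six-step stop-on-first-success mapping cascade.
#
#   1. drugname vs preferred terms + synonyms, iterating the clean-cascade
#      variants least-destructive-first;
#   2. active ingredients (prod_ai), with FAERS multi-ingredient splitting;
#   3. drugname vs the brand registry, then the registered ingredient name;
#   4. NDA number vs the NDA table, then the registered ingredient name;
#   5. word splitting: per-token lookup against multi-ingredient, ingredient
#      and brand-name concepts;
#   6. the custom verbatim mapping list.
#
# A step whose hits all roll up to the empty set (e.g. a bare dose form) is
# treated as failed and the cascade continues; this keeps "mapped" and
# "has ingredient-level concepts" synonymous.

STEP_LABELS <- c("NAME_MATCH", "ACTIVE_INGREDIENT", "BRAND_REGISTRY",
                 "NDA", "WORD_SPLIT", "CUSTOM")

#' Mapping options
#'
#' @param expand_ingredients replace a final multiple-ingredients concept by
#'   its single ingredients in the reported final concept set.
#' @param use_synonyms match against synonyms as well as preferred terms in
#'   steps 1 and 2.
#' @param steps which cascade steps (1..6) to attempt; mainly for ablation
#'   analyses.
#' @param min_token_chars minimum token length considered by word-split
#'   matching.
#' @return a list of options for [map_record()].
#' @export
map_options <- function(expand_ingredients = FALSE, use_synonyms = TRUE,
                        steps = 1:6, min_token_chars = 3L) {
  list(expand_ingredients = isTRUE(expand_ingredients),
       use_synonyms = isTRUE(use_synonyms),
       steps = as.integer(steps),
       min_token_chars = as.integer(min_token_chars))
}

# best concept among ids under the vocabulary tie-break, restricted to
# concepts with a non-empty roll-up; NULL when none qualifies
best_rollable <- function(index, ids) {
  for (id in order_by_priority(index, ids)) {
    if (length(roll_up(id, index))) return(id)
  }
  NULL
}

#' Custom-list lookup
#'
#' Verbatim (case-insensitive, trimmed) match against the custom
#' drugname-to-concept list; no cleaning variants are applied.
#'
#' @param index a `vocab_index`.
#' @param name drug name string.
#' @return a concept id, or `NULL` when absent.
#' @export
custom_lookup <- function(index, name) {
  if (length(name) != 1L || is.na(name)) return(NULL)
  index$custom_env[[tolower(trimws(name))]]
}

#' Word-split matching
#'
#' Splits `name` on whitespace and looks each token up (canonical form)
#' against `MULTI_INGREDIENT`, `INGREDIENT` and `BRAND_NAME` concepts, in
#' that priority per token; per-token hits are unioned.  Tokens shorter than
#' `min_token_chars` and stopword tokens are skipped.
#'
#' @param name drug name string.
#' @param index a `vocab_index`.
#' @param min_token_chars minimum token length.
#' @return integer vector of concept ids (possibly empty).
#' @export
word_split_match <- function(name, index, min_token_chars = 3L) {
  if (length(name) != 1L || is.na(name)) return(integer(0))
  toks <- strsplit(collapse_ws(name), " ", fixed = TRUE)[[1L]]
  toks <- toks[nchar(toks) >= min_token_chars]
  toks <- toks[!(tolower(toks) %in% index$lexicons$stopwords)]
  out <- integer(0)
  for (tok in toks) {
    ids <- lookup_ids(index, tok)
    if (length(ids) == 0L) next
    tts <- concept_rows(index, ids)
    for (want in c("MULTI_INGREDIENT", "INGREDIENT", "BRAND_NAME")) {
      hit <- tts[term_type == want, concept_id]
      if (length(hit)) { out <- c(out, hit); break }
    }
  }
  sort(unique(out))
}

# match one name through the clean cascade against the name index; returns
# list(id, variant) or NULL
match_name_cascade <- function(index, name, use_synonyms, notes_env, step_tag) {
  cc <- clean_cascade(name, index$lexicons)
  for (i in seq_len(nrow(cc))) {
    ids <- lookup_ids(index, cc$text[i], synonyms = use_synonyms)
    if (length(ids)) {
      best <- best_rollable(index, ids)
      if (!is.null(best))
        return(list(id = best, variant = cc$text[i], stage = cc$stage[i]))
      note(notes_env, step_tag, "hit(s) at stage ", cc$stage[i],
           " rolled up to nothing; continuing")
    }
  }
  NULL
}

note <- function(env, step, ...) {
  env$notes <- c(env$notes, paste0(step, ": ", paste0(..., collapse = "")))
}

#' Map one FAERS drug record through the cascade
#'
#' Attempts the six steps in order and stops at the first success.  The
#' returned result is a full audit of the attempt: which step matched, the
#' cleaned variant that matched, the raw matched concept(s), the rolled-up
#' concept(s), the resolved ATC code (or `NA` for abstention), and a note
#' trail of everything consulted.  Mapping failure is a result state
#' (`UNMAPPED`), never an error.
#'
#' @param record one-row data.frame / named list with the seven key fields
#'   (see [KEY_FIELDS]).
#' @param index a `vocab_index`.
#' @param options see [map_options()].
#' @return an object of class `mapping_result`: a list with elements `key`,
#'   `matched_step` (1..6 or `NA`), `step_label`, `variant_used`,
#'   `raw_concepts`, `rolled_concepts`, `final_concepts`, `atc_code`,
#'   `notes`.
#' @export
map_record <- function(record, index, options = map_options()) {
  rec <- as.list(record)
  key <- record_key(rec)
  drugname <- key[["drugname"]]
  ne <- new.env(parent = emptyenv()); ne$notes <- character(0)

  matched_step <- NA_integer_
  variant_used <- NA_character_
  raw <- integer(0)
  rolled <- integer(0)
  partial <- FALSE

  step_on <- function(k) k %in% options$steps

  # -- step 1: drugname vs preferred terms + synonyms ----------------------
  if (is.na(matched_step) && step_on(1L) && !is.na(drugname)) {
    m <- match_name_cascade(index, drugname, options$use_synonyms, ne, "step1")
    if (!is.null(m)) {
      matched_step <- 1L; variant_used <- m$variant
      raw <- m$id; rolled <- roll_up(m$id, index)
      note(ne, "step1", "matched '", m$variant, "' (stage ", m$stage,
           ") to concept ", m$id)
    } else note(ne, "step1", "no match for any cleaned variant")
  }

  # -- step 2: active ingredients (prod_ai) --------------------------------
  prod_ai <- key[["prod_ai"]]
  if (is.na(matched_step) && step_on(2L) && !is.na(prod_ai)) {
    parts <- trimws(strsplit(prod_ai, "\\\\|;")[[1L]])
    parts <- parts[nzchar(parts)]
    part_ids <- integer(0)
    n_fail <- 0L
    for (p in parts) {
      m <- match_name_cascade(index, p, options$use_synonyms, ne, "step2")
      if (!is.null(m)) part_ids <- c(part_ids, m$id) else n_fail <- n_fail + 1L
    }
    if (length(part_ids)) {
      matched_step <- 2L; variant_used <- prod_ai
      raw <- sort(unique(part_ids))
      ings <- ingredient_level(unlist(lapply(raw, roll_up, index = index)), index)
      if (length(ings) > 1L) {
        multi <- index$multi_for_set[[ids_chr(ings)]]
        rolled <- if (!is.null(multi)) as.integer(multi) else ings
      } else rolled <- ings
      if (n_fail > 0L) {
        partial <- TRUE
        note(ne, "step2", "partial: ", n_fail, " of ", length(parts),
             " ingredient part(s) unmatched")
      }
      note(ne, "step2", "matched prod_ai to concept(s) ", ids_chr(raw))
    } else if (length(parts)) note(ne, "step2", "no match for prod_ai")
  }

  # -- step 3: brand registry ----------------------------------------------
  if (is.na(matched_step) && step_on(3L) && !is.na(drugname)) {
    cc <- clean_cascade(drugname, index$lexicons)
    for (i in seq_len(nrow(cc))) {
      ing_name <- brand_to_ingredient(index, cc$text[i])
      if (is.na(ing_name)) next
      best <- best_rollable(index, lookup_ids(index, ing_name))
      if (!is.null(best)) {
        matched_step <- 3L; variant_used <- cc$text[i]
        raw <- best; rolled <- roll_up(best, index)
        note(ne, "step3", "registry brand '", cc$text[i], "' -> ingredient '",
             ing_name, "' -> concept ", best)
        break
      }
      note(ne, "step3", "registry ingredient '", ing_name,
           "' not found in vocabulary; continuing")
    }
    if (is.na(matched_step)) note(ne, "step3", "no registry match")
  }

  # -- step 4: NDA number --------------------------------------------------
  if (is.na(matched_step) && step_on(4L) && !is.na(key[["nda_num"]])) {
    ing_name <- nda_lookup(index, key[["nda_num"]])
    if (!is.na(ing_name)) {
      best <- best_rollable(index, lookup_ids(index, ing_name))
      if (!is.null(best)) {
        matched_step <- 4L; variant_used <- key[["nda_num"]]
        raw <- best; rolled <- roll_up(best, index)
        note(ne, "step4", "NDA ", key[["nda_num"]], " -> ingredient '",
             ing_name, "' -> concept ", best)
      } else note(ne, "step4", "NDA ingredient '", ing_name, "' not in vocabulary")
    } else note(ne, "step4", "no NDA match")
  }

  # -- step 5: word splitting ----------------------------------------------
  if (is.na(matched_step) && step_on(5L) && !is.na(drugname)) {
    cc <- clean_cascade(drugname, index$lexicons)
    cleaned <- cc$text[nrow(cc)]
    ids <- word_split_match(cleaned, index, options$min_token_chars)
    rl <- integer(0)
    keep <- integer(0)
    for (id in ids) {
      r <- roll_up(id, index)
      if (length(r)) { keep <- c(keep, id); rl <- c(rl, r) }
    }
    if (length(keep)) {
      matched_step <- 5L; variant_used <- cleaned
      raw <- sort(unique(keep)); rolled <- sort(unique(rl))
      note(ne, "step5", "word-split matched token concept(s) ", ids_chr(raw))
    } else note(ne, "step5", "no word-split match")
  }

  # -- step 6: custom list -------------------------------------------------
  if (is.na(matched_step) && step_on(6L) && !is.na(drugname)) {
    id <- custom_lookup(index, drugname)
    if (!is.null(id) && length(roll_up(id, index))) {
      matched_step <- 6L; variant_used <- drugname
      raw <- as.integer(id); rolled <- roll_up(id, index)
      note(ne, "step6", "custom list matched concept ", id)
    } else note(ne, "step6", "no custom match")
  }

  final <- rolled
  if (options$expand_ingredients && length(rolled))
    final <- ingredient_level(rolled, index)

  atc <- NA_character_
  if (!is.na(matched_step)) {
    comp <- derive_components_impl(rec, rolled, raw, index, notes_env = ne)
    refined <- refine_to_clinical_drug(comp, index)
    if (!is.null(refined))
      note(ne, "atc", "refined to clinical drug concept ", refined$concept_id)
    atc <- resolve_atc(comp, refined, index, key_ids = rolled, notes_env = ne)
  }

  structure(list(
    key = key,
    matched_step = matched_step,
    step_label = if (is.na(matched_step)) "UNMAPPED" else STEP_LABELS[matched_step],
    variant_used = variant_used,
    raw_concepts = raw,
    rolled_concepts = rolled,
    final_concepts = final,
    partial = partial,
    atc_code = atc,
    notes = ne$notes
  ), class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("<mapping_result>", x$step_label,
      if (!is.na(x$matched_step)) paste0("(step ", x$matched_step, ")") else "",
      "\n  final concepts:", if (length(x$final_concepts)) ids_chr(x$final_concepts) else "none",
      "\n  ATC:", if (is.na(x$atc_code)) "abstained" else x$atc_code, "\n")
  invisible(x)
}

#' Map a corpus of drug records
#'
#' Groups records into unique records (see [unique_records()]), maps each
#' unique record once, and returns the mapping table.
#'
#' @param records data.table of parsed records.
#' @param index a `vocab_index`.
#' @param options see [map_options()].
#' @return a `data.table` with the seven key fields, `n` (record
#'   multiplicity), `matched_step`, `step_label`, `variant_used`,
#'   `raw_concept_ids`, `final_concept_ids`, `atc_code`, `notes`.
#' @export
map_records <- function(records, index, options = map_options()) {
  uq <- unique_records(records)
  n_uq <- nrow(uq)
  res <- vector("list", n_uq)
  for (i in seq_len(n_uq)) {
    r <- map_record(uq[i], index, options)
    res[[i]] <- data.table(
      matched_step = r$matched_step,
      step_label = r$step_label,
      variant_used = r$variant_used,
      raw_concept_ids = ids_chr(r$raw_concepts),
      final_concept_ids = ids_chr(r$final_concepts),
      atc_code = r$atc_code,
      notes = paste(r$notes, collapse = " | ")
    )
  }
  cbind(uq, rbindlist(res))
}
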