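# Synthetic fixtures: toy vocabularies, registries, crosswalks and FAERS
# drug files with planted ground truth.
#
# The generator is the oracle: every record it emits is planted so that the
# expected cascade outcome (matched step, rolled-up concepts, ATC code or
# abstention) is known analytically at generation time, before the pipeline
# ever runs.  Ground truth is written to a separate file, never embedded in
# the FAERS file itself.
#
# The core vocabulary always contains the two classic ambiguous-ATC cases:
# a route-split beta-blocker (timolol: oral C07AA06 vs ophthalmic S01ED01)
# and a strength-split ingredient (finasteride: low-dose D11AX10 vs
# high-dose G04CB01), plus a combination product with a crosswalk entry, one
# without, an ingredient absent from the crosswalk, and an unspecific
# ingredient with two indistinguishable codes.

.SYLLABLES <- c("al", "an", "ar", "bel", "bor", "cal", "dar", "del", "dor",
                "fal", "fen", "gal", "lan", "lor", "mar", "mel", "nar", "nel",
                "par", "pel", "ral", "rel", "san", "sel", "tal", "tel", "van",
                "vel", "zan", "zel")
.SUFFIXES <- c("ol", "ine", "ide", "one", "pril", "mab", "zole", "micin")
.BRAND_SUFFIXES <- c("ex", "or", "an", "il", "ax")

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Noise specification for the FAERS fixture generator
#'
#' Probabilities controlling which mapping channel each generated record
#' exercises and which surface perturbations are applied to its drug name.
#' The defaults are the package's standard study conditions: a corpus where
#' most records carry a matchable name with realistic FAERS noise, a
#' minority exercise the later cascade steps, and a small fraction are
#' planted-unmappable misspellings.
#'
#' @param case_change,dosage_suffix,route_suffix,parenthetical,trailing_punct
#'   per-record probabilities of the respective drugname perturbations.
#' @param synonym_sub probability that a name record uses a synonym instead
#'   of the preferred term.
#' @param brand_sub probability that a record uses a brand name.
#' @param prod_ai_only probability of a record mappable only through its
#'   `prod_ai` field (step 2).
#' @param nda_only probability of a record mappable only through its NDA
#'   number (step 4).
#' @param misspelling probability of a planted-unmappable misspelled name.
#' @param custom_entry probability of a custom-list record (step 6).
#' @param word_split probability of a word-split record (step 5).
#' @param missing_evidence probability that a record's route/dose evidence is
#'   withheld (forcing abstention for ambiguous ingredients).
#' @param duplicate probability that a record duplicates an earlier one
#'   (same 7-field key).
#' @param seed optional seed stored with the spec.
#' @return a list of class `noise_spec`.
#' @export
noise_spec <- function(case_change = 0.5, dosage_suffix = 0.25,
                       route_suffix = 0.15, parenthetical = 0.10,
                       trailing_punct = 0.20, synonym_sub = 0.15,
                       brand_sub = 0.15, prod_ai_only = 0.10,
                       nda_only = 0.05, misspelling = 0.05,
                       custom_entry = 0.03, word_split = 0.05,
                       missing_evidence = 0.30, duplicate = 0.08,
                       seed = NULL) {
  spec <- list(case_change = case_change, dosage_suffix = dosage_suffix,
               route_suffix = route_suffix, parenthetical = parenthetical,
               trailing_punct = trailing_punct, synonym_sub = synonym_sub,
               brand_sub = brand_sub, prod_ai_only = prod_ai_only,
               nda_only = nda_only, misspelling = misspelling,
               custom_entry = custom_entry, word_split = word_split,
               missing_evidence = missing_evidence, duplicate = duplicate,
               seed = seed)
  bad <- vapply(spec[setdiff(names(spec), "seed")],
                function(p) !is.numeric(p) || p < 0 || p > 1, logical(1))
  if (any(bad)) stop("noise_spec: probabilities must lie in [0, 1]: ",
                     paste(names(bad)[bad], collapse = ", "))
  structure(spec, class = "noise_spec")
}

new_token <- function(taken, make, lexicons) {
  banned <- c(lexicons$routes, lexicons$stopwords, lexicons$units)
  for (try in 1:200) {
    x <- make()
    cx <- canonical_form(x, lexicons)
    toks <- strsplit(cx, " ", fixed = TRUE)[[1L]]
    if (!(cx %in% taken) && !any(toks %in% banned) && nchar(cx) >= 4L) return(x)
  }
  stop("could not generate a fresh unique token after 200 tries")
}

#' Generate a toy vocabulary directory with planted ground truth
#'
#' Writes the full set of delimited vocabulary tables consumed by
#' [load_vocab()] (concept, synonym, relationship, strength, brand registry,
#' NDA table, custom mappings, ATC crosswalk), plus two fixtures-only files:
#' `ledger.tsv`, listing every plantable name with its intended concept and
#' cascade step, and `atc_plan.tsv`, listing the evidence options and
#' expected ATC outcome for every ingredient-level concept.  The same seed
#' produces byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param n_extra number of additional randomly named ingredients beyond the
#'   fixed core (>= 0).
#' @param seed integer seed.
#' @param lexicons normalizer lexicons.
#' @return invisibly, a list with `dir`, `ledger`, `atc_plan`, `all_canon`.
#' @export
generate_vocabulary <- function(dir, n_extra = 20L, seed = 1L,
                                lexicons = normalizer_lexicons()) {
  if (n_extra < 0) stop("generate_vocabulary: n_extra must be >= 0")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, generate_vocabulary_impl(dir, as.integer(n_extra), lexicons))
}

generate_vocabulary_impl <- function(dir, n_extra, lexicons) {
  con <- list(); syn <- list(); rel <- list(); str_ <- list()
  reg <- list(); nda <- list(); cus <- list(); cw <- list()
  ledger <- list(); plan <- list()

  add_con <- function(id, name, vocab = "STANDARD_DRUG", tt = "INGREDIENT",
                      standard = TRUE, code = NA_character_) {
    con[[length(con) + 1L]] <<- data.table(
      concept_id = id, concept_name = name, vocabulary = vocab,
      term_type = tt, standard = standard, concept_code = code)
  }
  add_rel <- function(s, t, k) {
    rel[[length(rel) + 1L]] <<- data.table(source_id = s, target_id = t, kind = k)
  }
  add_plant <- function(channel, text, concept_id, step, rolled, atc_key) {
    ledger[[length(ledger) + 1L]] <<- data.table(
      channel = channel, text = text, concept_id = concept_id,
      expected_step = step, rolled = rolled, atc_key = atc_key)
  }
  add_plan <- function(atc_key, route = NA_character_, dose_amt = NA_character_,
                       dose_unit = NA_character_, dose_form = NA_character_,
                       expected_atc = NA_character_) {
    plan[[length(plan) + 1L]] <<- data.table(
      atc_key = atc_key, route = route, dose_amt = dose_amt,
      dose_unit = dose_unit, dose_form = dose_form, expected_atc = expected_atc)
  }
  add_cw <- function(id, code, route = "ANY", smin = NA_real_, smax = NA_real_,
                     sunit = NA_character_) {
    cw[[length(cw) + 1L]] <<- data.table(
      ingredient_concept_id = id, atc_code = code, route_class = route,
      strength_min = smin, strength_max = smax, strength_unit = sunit)
  }

  # ---- fixed core ---------------------------------------------------------
  core <- c(Timolol = 1001L, Finasteride = 1002L, Diltiazem = 1003L,
            Aspirin = 1004L, Caffeine = 1005L, Hydrochlorothiazide = 1006L,
            Losartan = 1007L, Calcium = 1008L)
  for (nm in names(core)) add_con(core[[nm]], nm)
  add_con(1009L, "Nimotuzumab", vocab = "DRUG_EXTENSION")  # no crosswalk entry

  add_con(2001L, "Aspirin / Caffeine", tt = "MULTI_INGREDIENT")
  add_rel(2001L, 1004L, "CONSISTS_OF"); add_rel(2001L, 1005L, "CONSISTS_OF")
  add_con(2002L, "Hydrochlorothiazide / Losartan", tt = "MULTI_INGREDIENT")
  add_rel(2002L, 1006L, "CONSISTS_OF"); add_rel(2002L, 1007L, "CONSISTS_OF")

  add_con(3001L, "Cardizem", tt = "BRAND_NAME")
  add_rel(3001L, 1003L, "HAS_INGREDIENT")
  add_con(3002L, "Propecia", tt = "BRAND_NAME")
  add_rel(3002L, 1002L, "HAS_INGREDIENT")

  add_con(6001L, "Oral Tablet", tt = "DOSE_FORM")
  add_con(6002L, "Ophthalmic Solution", tt = "DOSE_FORM")

  add_con(4001L, "Finasteride 1 MG Oral Tablet", tt = "CLINICAL_DRUG")
  add_rel(4001L, 1002L, "HAS_INGREDIENT"); add_rel(4001L, 6001L, "HAS_DOSE_FORM")
  str_[[length(str_) + 1L]] <- data.table(drug_concept_id = 4001L,
                                          ingredient_concept_id = 1002L,
                                          amount = 1, unit = "MG")
  add_con(4002L, "Finasteride 5 MG Oral Tablet", tt = "CLINICAL_DRUG")
  add_rel(4002L, 1002L, "HAS_INGREDIENT"); add_rel(4002L, 6001L, "HAS_DOSE_FORM")
  str_[[length(str_) + 1L]] <- data.table(drug_concept_id = 4002L,
                                          ingredient_concept_id = 1002L,
                                          amount = 5, unit = "MG")
  add_con(5001L, "Aspirin / Caffeine Oral Tablet", tt = "CLINICAL_DRUG_FORM")
  add_rel(5001L, 1004L, "HAS_INGREDIENT"); add_rel(5001L, 1005L, "HAS_INGREDIENT")
  add_rel(5001L, 6001L, "HAS_DOSE_FORM")
  add_con(5002L, "Timolol Ophthalmic Solution", tt = "CLINICAL_DRUG_FORM")
  add_rel(5002L, 1001L, "HAS_INGREDIENT"); add_rel(5002L, 6002L, "HAS_DOSE_FORM")

  # a few ATC concepts (code-bearing; not name-indexed)
  atc_codes <- c(C07AA06 = 9001L, S01ED01 = 9002L, D11AX10 = 9003L,
                 G04CB01 = 9004L, C09DA01 = 9005L)
  for (code in names(atc_codes))
    add_con(atc_codes[[code]], paste("ATC", code), vocab = "ATC",
            tt = "ATC_5TH", standard = FALSE, code = code)

  syn[[length(syn) + 1L]] <- data.table(
    concept_id = c(1001L, 1002L, 1003L, 1004L),
    synonym = c("Timololum", "Finasteridum", "Diltiazemum",
                "Acetylsalicylic acid"))

  reg[[length(reg) + 1L]] <- data.table(
    brand = c("Cardizem", "Tensiolol", "Prostakur"),
    ingredient_name = c("Diltiazem", "Timolol", "Finasteride"))

  nda[[length(nda) + 1L]] <- data.table(
    nda_num = c("020702", "021500"),
    ingredient_name = c("Timolol", "Aspirin"))

  # crosswalk: route-split, strength-split, combination, unspecific
  add_cw(1001L, "C07AA06", route = "ORAL")
  add_cw(1001L, "S01ED01", route = "OPHTHALMIC")
  add_cw(1002L, "D11AX10", smin = 0, smax = 2, sunit = "MG")
  add_cw(1002L, "G04CB01", smin = 2.5, smax = NA_real_, sunit = "MG")
  add_cw(1003L, "C08DB01")
  add_cw(1004L, "B01AC06")
  add_cw(1005L, "N06BC01")
  add_cw(1006L, "C03AA03")
  add_cw(1007L, "C09CA01")
  add_cw(1008L, "A12AA04"); add_cw(1008L, "A12AA20")  # never disambiguable
  add_cw(2002L, "C09DA01")                            # combination entry

  # ---- randomly named extra ingredients ----------------------------------
  taken <- new.env(parent = emptyenv())
  register <- function(x) assign(canonical_form(x, lexicons), TRUE, envir = taken)
  taken_set <- function() ls(taken)
  for (l in con) register(l$concept_name)
  register("Tensiolol"); register("Prostakur")
  for (s in syn) for (x in s$synonym) register(x)

  mk_ing <- function() cap1(paste0(paste(sample(.SYLLABLES, 3, replace = TRUE),
                                         collapse = ""), sample(.SUFFIXES, 1)))
  mk_brand <- function() cap1(paste0(paste(sample(.SYLLABLES, 2, replace = TRUE),
                                           collapse = ""), sample(.BRAND_SUFFIXES, 1)))
  mk_code <- function(existing) {
    repeat {
      code <- sprintf("%s%02d%s%02d", sample(LETTERS, 1), sample(0:99, 1),
                      paste(sample(LETTERS, 2, replace = TRUE), collapse = ""),
                      sample(0:99, 1))
      if (!code %in% existing) return(code)
    }
  }
  used_nda <- c(20702L, 21500L)
  extra_ids <- if (n_extra > 0L) 1100L + seq_len(n_extra) else integer(0)
  for (i in seq_along(extra_ids)) {
    id <- extra_ids[i]
    nm <- new_token(taken_set(), mk_ing, lexicons); register(nm)
    add_con(id, nm)
    no_cw <- (i %% 9L == 0L)
    if (!no_cw) {
      code <- mk_code(vapply(cw, function(x) x$atc_code, character(1)))
      add_cw(id, code)
      add_plan(id, expected_atc = code)
      add_plan(id, route = "ORAL", expected_atc = code)
    } else {
      add_plan(id)
    }
    rolled <- as.character(id)
    add_plant("name", nm, id, 1L, rolled, id)
    add_plant("prod_ai_single", nm, id, 2L, rolled, id)
    if (i %% 4L == 0L) {
      s <- new_token(taken_set(),
                     function() paste0(nm, sample(c("um", "ium", "etum"), 1)),
                     lexicons)
      register(s)
      syn[[length(syn) + 1L]] <- data.table(concept_id = id, synonym = s)
      add_plant("synonym", s, id, 1L, rolled, id)
    }
    if (i %% 5L == 0L) {
      b <- new_token(taken_set(), mk_brand, lexicons); register(b)
      reg[[length(reg) + 1L]] <- data.table(brand = b, ingredient_name = nm)
      add_plant("registry_brand", b, id, 3L, rolled, id)
    }
    if (i %% 6L == 0L) {
      num <- sample(setdiff(10000:99999, used_nda), 1L)
      used_nda <- c(used_nda, num)
      nda[[length(nda) + 1L]] <- data.table(nda_num = sprintf("%06d", num),
                                            ingredient_name = nm)
      add_plant("nda", as.character(num), id, 4L, rolled, id)
    }
    if (i %% 7L == 0L) {
      jt <- new_token(taken_set(), function()
        paste0("QX", paste(sample(LETTERS, 5, replace = TRUE), collapse = "")),
        lexicons)
      register(jt)
      v <- sprintf("%s MIXTURE PREPARATION NO%d", jt, i)
      cus[[length(cus) + 1L]] <- data.table(verbatim_name = v, concept_id = id)
      add_plant("custom", v, id, 6L, rolled, id)
    }
    if (i %% 3L == 0L) {
      jt <- new_token(taken_set(), function()
        paste0("QZ", paste(sample(LETTERS, 5, replace = TRUE), collapse = "")),
        lexicons)
      add_plant("word_split", paste(jt, nm), id, 5L, rolled, id)
    }
  }

  # ---- core plants --------------------------------------------------------
  for (nm in names(core))
    add_plant("name", nm, core[[nm]], 1L, as.character(core[[nm]]), core[[nm]])
  add_plant("name", "Nimotuzumab", 1009L, 1L, "1009", 1009L)
  add_plant("name", "Aspirin / Caffeine", 2001L, 1L, "2001", 2001L)
  add_plant("name", "Hydrochlorothiazide / Losartan", 2002L, 1L, "2002", 2002L)
  add_plant("name", "Cardizem", 3001L, 1L, "1003", 1003L)
  add_plant("name", "Propecia", 3002L, 1L, "1002", 1002L)
  add_plant("name", "Finasteride 1 MG Oral Tablet", 4001L, 1L, "1002", 1002L)
  add_plant("name", "Finasteride 5 MG Oral Tablet", 4002L, 1L, "1002", 1002L)
  add_plant("name", "Aspirin / Caffeine Oral Tablet", 5001L, 1L, "2001", 2001L)
  add_plant("synonym", "Timololum", 1001L, 1L, "1001", 1001L)
  add_plant("synonym", "Finasteridum", 1002L, 1L, "1002", 1002L)
  add_plant("synonym", "Diltiazemum", 1003L, 1L, "1003", 1003L)
  add_plant("synonym", "Acetylsalicylic acid", 1004L, 1L, "1004", 1004L)
  add_plant("registry_brand", "Tensiolol", 1001L, 3L, "1001", 1001L)
  add_plant("registry_brand", "Prostakur", 1002L, 3L, "1002", 1002L)
  add_plant("nda", "020702", 1001L, 4L, "1001", 1001L)
  add_plant("nda", "21500", 1004L, 4L, "1004", 1004L)
  cus[[length(cus) + 1L]] <- data.table(
    verbatim_name = "ZZQ HEADACHE MIXTURE NO7", concept_id = 1004L)
  add_plant("custom", "ZZQ HEADACHE MIXTURE NO7", 1004L, 6L, "1004", 1004L)
  for (nm in c("Timolol", "Aspirin", "Hydrochlorothiazide")) {
    jt <- new_token(taken_set(), function()
      paste0("QZ", paste(sample(LETTERS, 5, replace = TRUE), collapse = "")),
      lexicons)
    add_plant("word_split", paste(jt, nm), core[[nm]], 5L,
              as.character(core[[nm]]), core[[nm]])
  }
  add_plant("prod_ai_single", "Timolol", 1001L, 2L, "1001", 1001L)
  add_plant("prod_ai_single", "Finasteride", 1002L, 2L, "1002", 1002L)
  add_plant("prod_ai_single", "Diltiazem", 1003L, 2L, "1003", 1003L)
  add_plant("prod_ai_single", "Calcium", 1008L, 2L, "1008", 1008L)
  add_plant("prod_ai_multi", "Aspirin\\Caffeine", 2001L, 2L, "2001", 2001L)
  add_plant("prod_ai_multi", "Hydrochlorothiazide\\Losartan", 2002L, 2L,
            "2002", 2002L)
  jt <- new_token(taken_set(), function()
    paste0("QX", paste(sample(LETTERS, 5, replace = TRUE), collapse = "")),
    lexicons)
  add_plant("prod_ai_partial", paste0("Aspirin\\", jt), 1004L, 2L, "1004", 1004L)
  for (nm in c("Timolol", "Finasteride", "Diltiazem", "Aspirin"))
    add_plant("misspell", nm, NA_integer_, NA_integer_, "", NA_integer_)

  # ---- ATC evidence plans for the core -----------------------------------
  add_plan(1001L, route = "ORAL", expected_atc = "C07AA06")
  add_plan(1001L, route = "OPHTHALMIC", expected_atc = "S01ED01")
  add_plan(1001L, route = "TOPICAL")
  add_plan(1001L)
  add_plan(1001L, dose_form = "OPHTHALMIC SOLUTION", expected_atc = "S01ED01")
  add_plan(1002L, dose_amt = "1", dose_unit = "MG", expected_atc = "D11AX10")
  add_plan(1002L, dose_amt = "5", dose_unit = "MG", expected_atc = "G04CB01")
  add_plan(1002L, route = "ORAL", dose_amt = "5", dose_unit = "MG",
           expected_atc = "G04CB01")
  add_plan(1002L)
  add_plan(1003L, expected_atc = "C08DB01")
  add_plan(1003L, route = "ORAL", expected_atc = "C08DB01")
  add_plan(1004L, expected_atc = "B01AC06")
  add_plan(1005L, expected_atc = "N06BC01")
  add_plan(1006L, expected_atc = "C03AA03")
  add_plan(1007L, expected_atc = "C09CA01")
  add_plan(1008L); add_plan(1008L, route = "ORAL")
  add_plan(1009L)
  add_plan(2001L)
  add_plan(2002L, expected_atc = "C09DA01")

  # ---- write tables -------------------------------------------------------
  wr <- function(x, f) {
    dt <- rbindlist(x)
    fwrite(dt, file.path(dir, f), sep = "\t", quote = FALSE, na = "")
    dt
  }
  con_dt <- wr(con, "concept.tsv")
  syn_dt <- wr(syn, "synonym.tsv")
  wr(rel, "relationship.tsv")
  wr(str_, "strength.tsv")
  reg_dt <- wr(reg, "brand_registry.tsv")
  wr(nda, "nda.tsv")
  cus_dt <- wr(cus, "custom_mappings.tsv")
  wr(cw, "atc_crosswalk.tsv")
  ledger_dt <- wr(ledger, "ledger.tsv")
  plan_dt <- wr(plan, "atc_plan.tsv")

  all_canon <- unique(c(
    canonical_form(con_dt$concept_name, lexicons),
    canonical_form(syn_dt$synonym, lexicons),
    canonical_form(reg_dt$brand, lexicons),
    canonical_form(cus_dt$verbatim_name, lexicons)))

  invisible(list(dir = dir, ledger = ledger_dt, atc_plan = plan_dt,
                 all_canon = all_canon))
}

#' Apply sampled surface noise to a drug name
#'
#' Applies the drawn perturbations in fixed order (case change, dosage
#' suffix, route suffix, parenthetical, trailing punctuation) using the
#' session RNG, and records which were applied.  Every perturbation is
#' invertible by the cleaning cascade, which is what makes the generator's
#' expected outcomes sound.
#'
#' @param name the clean planted name.
#' @param noise a [noise_spec()].
#' @param allowed which perturbations may apply (custom-list records, for
#'   instance, only tolerate case changes because custom matching is
#'   verbatim).
#' @return list with `text` and `ops` (character vector of applied ops).
#' @export
perturb_name <- function(name, noise = noise_spec(),
                         allowed = c("case", "dosage", "route", "paren",
                                     "trailing")) {
  ops <- character(0)
  out <- name
  if ("case" %in% allowed && runif(1) < noise$case_change) {
    out <- if (runif(1) < 0.5) toupper(out) else tolower(out)
    ops <- c(ops, "case")
  }
  if ("dosage" %in% allowed && runif(1) < noise$dosage_suffix) {
    out <- paste0(out, sample(c(" 500MG", " 10 MG", " 0.5%", " 250 MG",
                                " 20 ML"), 1))
    ops <- c(ops, "dosage")
  }
  if ("route" %in% allowed && runif(1) < noise$route_suffix) {
    out <- paste0(out, sample(c(" ORAL", " ORAL TABLET", " TABLET",
                                " INJECTION", " CAPSULE"), 1))
    ops <- c(ops, "route")
  }
  if ("paren" %in% allowed && runif(1) < noise$parenthetical) {
    out <- paste0(out, sample(c(" (UNKNOWN)", " (SEE IMAGE)", " (1 BOTTLE)"), 1))
    ops <- c(ops, "paren")
  }
  if ("trailing" %in% allowed && runif(1) < noise$trailing_punct) {
    out <- paste0(out, sample(c(".", " ..", "  "), 1))
    ops <- c(ops, "trailing")
  }
  list(text = out, ops = ops)
}

# single-character transposition verified absent from every indexed name
make_misspelling <- function(name, all_canon, lexicons) {
  chars <- strsplit(name, "")[[1L]]
  pos <- seq_len(length(chars) - 1L)
  for (i in sample(pos)) {
    if (chars[i] == chars[i + 1L]) next
    sw <- chars; sw[c(i, i + 1L)] <- sw[c(i + 1L, i)]
    cand <- paste(sw, collapse = "")
    if (!(canonical_form(cand, lexicons) %in% all_canon)) return(cand)
  }
  paste0(name, "qx")  # all transpositions collide; force a miss
}

ROUTE_FIELD_VARIANTS <- list(
  ORAL = c("ORAL", "Oral", "PO"),
  OPHTHALMIC = c("OPHTHALMIC", "OCULAR"),
  TOPICAL = c("TOPICAL", "CUTANEOUS"),
  PARENTERAL = c("INTRAVENOUS", "INTRAMUSCULAR"),
  RECTAL = "RECTAL", NASAL = "NASAL", VAGINAL = "VAGINAL",
  INHALATION = "INHALATION")

#' Generate a FAERS drug file with planted ground truth
#'
#' Samples `n` records from the vocabulary's plant ledger according to the
#' noise specification, applies invertible surface noise to the drug names,
#' fills the route/dose evidence fields from the ATC evidence plan, and
#' writes (a) a "$"-delimited FAERS-format drug file and (b) a separate
#' tab-delimited ground-truth table pairing each record line with its
#' expected matched step, rolled-up concepts and ATC outcome.
#'
#' @param path output path for the drug file.
#' @param n number of records.
#' @param vocab result of [generate_vocabulary()] (or a list with `ledger`,
#'   `atc_plan`, `all_canon`).
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param truth_path output path for the ground-truth table.
#' @param lexicons normalizer lexicons.
#' @return invisibly, a list with `path`, `truth_path`, `records`
#'   (data.table as written) and `truth` (the ground-truth data.table).
#' @export
generate_faers_file <- function(path, n, vocab, noise = noise_spec(),
                                seed = 1L,
                                truth_path = paste0(path, ".truth.tsv"),
                                lexicons = normalizer_lexicons()) {
  with_seed(seed,
            generate_faers_impl(path, n, vocab, noise, truth_path, lexicons))
}

generate_faers_impl <- function(path, n, vocab, noise, truth_path, lexicons) {
  ledger <- vocab$ledger
  plan <- vocab$atc_plan
  all_canon <- vocab$all_canon
  by_channel <- split(ledger, by = "channel")
  plan_by_key <- split(plan, by = "atc_key")

  junk_name <- function() {
    base <- ledger[channel == "misspell"][sample(.N, 1L), text]
    make_misspelling(base, all_canon, lexicons)
  }

  pick_plan <- function(key, withhold) {
    rows <- plan_by_key[[as.character(key)]]
    none <- rows[is.na(route) & is.na(dose_amt) & is.na(dose_form)]
    if (withhold && nrow(none)) return(none[1L])
    rows[sample(nrow(rows), 1L)]
  }

  recs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    if (i > 1L && runif(1) < noise$duplicate) {
      j <- sample(i - 1L, 1L)
      r <- copy(recs[[j]]); r[, report_id := sprintf("%d", 100000L + i)]
      recs[[i]] <- r
      t <- copy(truth[[j]]); t[, line := i]
      truth[[i]] <- t
      next
    }
    u <- runif(1)
    channel <-
      if (u < noise$misspelling) "misspell"
      else if (u < (p <- noise$misspelling + noise$prod_ai_only)) {
        v <- runif(1)
        if (v < 0.6) "prod_ai_single" else if (v < 0.85) "prod_ai_multi"
        else "prod_ai_partial"
      }
      else if (u < (p <- p + noise$nda_only)) "nda"
      else if (u < (p <- p + noise$custom_entry)) "custom"
      else if (u < (p <- p + noise$word_split)) "word_split"
      else if (u < (p <- p + noise$brand_sub)) {
        if (runif(1) < 0.5 || is.null(by_channel[["registry_brand"]]))
          "brand_vocab" else "registry_brand"
      }
      else if (u < p + noise$synonym_sub) "synonym"
      else "name"
    if (channel == "brand_vocab") {
      nm_plants <- by_channel[["name"]]
      brands <- nm_plants[concept_id %in% c(3001L, 3002L)]
      plant <- brands[sample(.N, 1L)]
      channel <- "name"
    } else {
      pool <- by_channel[[channel]]
      plant <- pool[sample(.N, 1L)]
    }

    drugname <- NA_character_; prod_ai <- NA_character_; nda_num <- NA_character_
    ops <- character(0)
    if (channel == "misspell") {
      drugname <- make_misspelling(plant$text, all_canon, lexicons)
      pb <- perturb_name(drugname, noise)
      drugname <- pb$text; ops <- c("misspell", pb$ops)
    } else if (channel %in% c("prod_ai_single", "prod_ai_multi", "prod_ai_partial")) {
      prod_ai <- plant$text
      if (runif(1) < 0.5) {
        drugname <- junk_name()
        pb <- perturb_name(drugname, noise)
        drugname <- pb$text; ops <- c("junk_drugname", pb$ops)
      }
    } else if (channel == "nda") {
      nda_num <- if (runif(1) < 0.5) sprintf("%06d", as.integer(gsub("[^0-9]", "", plant$text)))
                 else plant$text
      if (runif(1) < 0.5) {
        drugname <- junk_name()
        pb <- perturb_name(drugname, noise)
        drugname <- pb$text; ops <- c("junk_drugname", pb$ops)
      }
    } else if (channel == "custom") {
      pb <- perturb_name(plant$text, noise, allowed = "case")
      drugname <- pb$text; ops <- pb$ops
    } else {
      pb <- perturb_name(plant$text, noise)
      drugname <- pb$text; ops <- pb$ops
    }

    # evidence fields + expected ATC
    route <- NA_character_; dose_amt <- NA_character_
    dose_unit <- NA_character_; dose_form <- NA_character_
    expected_atc <- NA_character_
    if (!is.na(plant$atc_key)) {
      pr <- pick_plan(plant$atc_key, withhold = runif(1) < noise$missing_evidence)
      if (!is.na(pr$route))
        route <- sample(ROUTE_FIELD_VARIANTS[[pr$route]], 1L)
      dose_amt <- pr$dose_amt; dose_unit <- pr$dose_unit
      dose_form <- pr$dose_form
      expected_atc <- pr$expected_atc
    }
    # realism: name-matched records often carry prod_ai too (step 1 wins)
    if (channel %in% c("name", "synonym") && runif(1) < 0.3 &&
        !is.na(plant$atc_key) && plant$atc_key >= 1000L) {
      key_row <- ledger[channel == "prod_ai_single" & atc_key == plant$atc_key]
      if (nrow(key_row)) prod_ai <- key_row$text[1L]
    }

    recs[[i]] <- data.table(
      report_id = sprintf("%d", 100000L + i), drug_seq = "1",
      drugname = drugname, prod_ai = prod_ai, route = route,
      dose_amt = dose_amt, dose_form = dose_form, dose_unit = dose_unit,
      nda_num = nda_num)
    truth[[i]] <- data.table(
      line = i, channel = channel,
      expected_step = plant$expected_step,
      expected_concepts = plant$rolled,
      expected_atc = expected_atc,
      noise_ops = paste(ops, collapse = ";"))
  }
  records <- rbindlist(recs)
  truth <- rbindlist(truth)
  write_drug_file(records, path)
  fwrite(truth, truth_path, sep = "\t", quote = FALSE, na = "")
  invisible(list(path = path, truth_path = truth_path,
                 records = records, truth = truth))
}
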