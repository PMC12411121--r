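# Hand-built miniature vocabulary, written row by row so tests know exactly
# what is planted, independently of the fixtures generator.

library(data.table)

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

# Ingredients: timolol(11), finasteride(12), diltiazem(13), aspirin(14),
# caffeine(15).  Multi: aspirin/caffeine(21).  Brands: cardizem(31)->13,
# nococyl(32)->21.  Clinical drugs: finasteride 1mg(41), 5mg(42).
# CDF: aspirin/caffeine oral tablet(51).  Dose forms: oral tablet(61),
# ophthalmic solution(62).
tiny_vocab_dir <- function(dir = tempfile("tinyvocab")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(data.frame(
    concept_id = c(11, 12, 13, 14, 15, 21, 31, 32, 41, 42, 51, 61, 62),
    concept_name = c("Timolol", "Finasteride", "Diltiazem", "Aspirin",
                     "Caffeine", "Aspirin / Caffeine", "Cardizem", "Nococyl",
                     "Finasteride 1 MG Oral Tablet",
                     "Finasteride 5 MG Oral Tablet",
                     "Aspirin / Caffeine Oral Tablet",
                     "Oral Tablet", "Ophthalmic Solution"),
    vocabulary = "STANDARD_DRUG",
    term_type = c(rep("INGREDIENT", 5), "MULTI_INGREDIENT",
                  "BRAND_NAME", "BRAND_NAME", "CLINICAL_DRUG",
                  "CLINICAL_DRUG", "CLINICAL_DRUG_FORM",
                  "DOSE_FORM", "DOSE_FORM"),
    standard = TRUE,
    concept_code = NA_character_), dir, "concept.tsv")
  write_tsv(data.frame(
    concept_id = c(11, 14, 14),
    synonym = c("Timololum", "Acetylsalicylic acid", "ASPIRIN  (NSAID)")),
    dir, "synonym.tsv")
  write_tsv(data.frame(
    source_id = c(21, 21, 31, 32, 41, 41, 42, 42, 51, 51, 51),
    target_id = c(14, 15, 13, 21, 12, 61, 12, 61, 14, 15, 61),
    kind = c("CONSISTS_OF", "CONSISTS_OF", "HAS_INGREDIENT",
             "HAS_INGREDIENT", "HAS_INGREDIENT", "HAS_DOSE_FORM",
             "HAS_INGREDIENT", "HAS_DOSE_FORM", "HAS_INGREDIENT",
             "HAS_INGREDIENT", "HAS_DOSE_FORM")), dir, "relationship.tsv")
  write_tsv(data.frame(
    drug_concept_id = c(41, 42),
    ingredient_concept_id = c(12, 12),
    amount = c(1, 5),
    unit = c("MG", "MG")), dir, "strength.tsv")
  write_tsv(data.frame(
    brand = c("Cardizem", "Tensiolol"),
    ingredient_name = c("Diltiazem", "Timolol")), dir, "brand_registry.tsv")
  write_tsv(data.frame(
    nda_num = c("20702", "021500"),
    ingredient_name = c("Timolol", "Aspirin")), dir, "nda.tsv")
  write_tsv(data.frame(
    verbatim_name = "ZZQ HEADACHE MIXTURE NO7",
    concept_id = 14), dir, "custom_mappings.tsv")
  write_tsv(data.frame(
    ingredient_concept_id = c(11, 11, 12, 12, 13, 14, 15),
    atc_code = c("C07AA06", "S01ED01", "D11AX10", "G04CB01", "C08DB01",
                 "B01AC06", "N06BC01"),
    route_class = c("ORAL", "OPHTHALMIC", "ANY", "ANY", "ANY", "ANY", "ANY"),
    strength_min = c(NA, NA, 0, 2.5, NA, NA, NA),
    strength_max = c(NA, NA, 2, NA, NA, NA, NA),
    strength_unit = c(NA, NA, "MG", "MG", NA, NA, NA)), dir, "atc_crosswalk.tsv")
  dir
}

tiny_index <- local({
  idx <- NULL
  function() {
    if (is.null(idx)) idx <<- load_vocab(tiny_vocab_dir())
    idx
  }
})

# A drug record as a named list, all seven key fields defaulting to missing.
rec <- function(drugname = NA, prod_ai = NA, route = NA, dose_amt = NA,
                dose_form = NA, dose_unit = NA, nda_num = NA) {
  list(drugname = as.character(drugname), prod_ai = as.character(prod_ai),
       route = as.character(route), dose_amt = as.character(dose_amt),
       dose_form = as.character(dose_form), dose_unit = as.character(dose_unit),
       nda_num = as.character(nda_num))
}

# Per-line comparison of pipeline outcomes against generator ground truth;
# returns the line numbers that disagree.
truth_mismatches <- function(records, truth, mapping) {
  recs <- data.table::copy(records)
  recs[, line := .I]
  kj <- merge(recs, mapping, by = KEY_FIELDS, all.x = TRUE)
  data.table::setkey(kj, line)
  data.table::setkey(truth, line)
  ok <- ((is.na(truth$expected_step) & is.na(kj$matched_step)) |
         (!is.na(truth$expected_step) & !is.na(kj$matched_step) &
          truth$expected_step == kj$matched_step)) &
    data.table::fifelse(is.na(truth$expected_concepts) | truth$expected_concepts == "",
                        kj$final_concept_ids == "",
                        kj$final_concept_ids == truth$expected_concepts) &
    ((is.na(truth$expected_atc) & is.na(kj$atc_code)) |
     (!is.na(truth$expected_atc) & !is.na(kj$atc_code) &
      truth$expected_atc == kj$atc_code))
  ok[is.na(ok)] <- FALSE
  truth$line[!ok]
}
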