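test_that("generated vocabularies load cleanly and contain the planted cases", {
  v <- generate_vocabulary(tempfile("v"), n_extra = 15, seed = 5)
  idx <- load_vocab(v$dir)
  # route-split and strength-split ATC ingredients always present
  tim <- lookup_exact(idx, "Timolol")$concept_id
  fin <- lookup_exact(idx, "Finasteride")$concept_id
  expect_length(tim, 1L); expect_length(fin, 1L)
  expect_setequal(idx$crosswalk[ingredient_concept_id == tim, atc_code],
                  c("C07AA06", "S01ED01"))
  expect_setequal(idx$crosswalk[ingredient_concept_id == fin, atc_code],
                  c("D11AX10", "G04CB01"))
  # every ledger plant resolves to its intended concept via its channel
  lg <- v$ledger
  for (i in seq_len(nrow(lg))) {
    p <- lg[i]
    switch(p$channel,
      name = ,
      synonym = expect_true(p$concept_id %in% lookup_exact(idx, p$text)$concept_id),
      registry_brand = expect_false(is.na(brand_to_ingredient(idx, p$text))),
      nda = expect_false(is.na(nda_lookup(idx, p$text))),
      custom = expect_equal(custom_lookup(idx, p$text), p$concept_id),
      word_split = expect_true(p$concept_id %in% word_split_match(p$text, idx)),
      NULL)
  }
  # infeasible parameters rejected
  expect_error(generate_vocabulary(tempfile(), n_extra = -1), "n_extra")
})

test_that("generation is byte-deterministic under a seed", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_vocabulary(d1, n_extra = 8, seed = 9)
  generate_vocabulary(d2, n_extra = 8, seed = 9)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  v <- generate_vocabulary(tempfile(), n_extra = 8, seed = 9)
  g1 <- generate_faers_file(tempfile(), 60, v, seed = 10)
  g2 <- generate_faers_file(tempfile(), 60, v, seed = 10)
  expect_identical(readLines(g1$path), readLines(g2$path))
  expect_identical(g1$truth, g2$truth)
})

test_that("noise operations are invertible and misspellings truly miss", {
  v <- generate_vocabulary(tempfile(), n_extra = 10, seed = 13)
  idx <- load_vocab(v$dir)
  set.seed(99)
  # zero-noise: identity
  z <- noise_spec(case_change = 0, dosage_suffix = 0, route_suffix = 0,
                  parenthetical = 0, trailing_punct = 0)
  expect_equal(perturb_name("Timolol", z)$text, "Timolol")
  expect_length(perturb_name("Timolol", z)$ops, 0L)
  # dosage-injection only: the cascade recovers the base name
  d <- noise_spec(case_change = 0, dosage_suffix = 1, route_suffix = 0,
                  parenthetical = 0, trailing_punct = 0)
  for (i in 1:20) {
    p <- perturb_name("Timolol", d)
    cc <- clean_cascade(p$text)
    expect_equal(cc$text[nrow(cc)], "Timolol")
  }
  # misspellings never hit any indexed name
  for (base in c("Timolol", "Finasteride", "Aspirin")) {
    for (i in 1:10) {
      m <- faersmapr:::make_misspelling(base, v$all_canon, normalizer_lexicons())
      expect_false(canonical_form(m) %in% v$all_canon)
      expect_equal(nrow(lookup_exact(idx, m)), 0L)
    }
  }
  expect_error(noise_spec(case_change = 1.5), "\\[0, 1\\]")
})

test_that("extreme noise settings force the planted outcome", {
  v <- generate_vocabulary(tempfile(), n_extra = 10, seed = 17)
  idx <- load_vocab(v$dir)
  # all records planted unmappable
  g <- generate_faers_file(tempfile(), 40, v, seed = 18,
                           noise = noise_spec(misspelling = 1, duplicate = 0))
  m <- map_records(parse_drug_file(g$path), idx)
  expect_true(all(is.na(m$matched_step)))
  # no noise at all: everything maps at step 1
  g2 <- generate_faers_file(tempfile(), 40, v, seed = 19,
                            noise = noise_spec(case_change = 0, dosage_suffix = 0,
                                               route_suffix = 0, parenthetical = 0,
                                               trailing_punct = 0, synonym_sub = 0,
                                               brand_sub = 0, prod_ai_only = 0,
                                               nda_only = 0, misspelling = 0,
                                               custom_entry = 0, word_split = 0,
                                               duplicate = 0))
  recs <- parse_drug_file(g2$path)
  m2 <- map_records(recs, idx)
  expect_true(all(m2$matched_step == 1L))
  expect_length(truth_mismatches(recs, g2$truth, m2), 0L)
})
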