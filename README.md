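# faersmapr

Drug names in the FDA Adverse Event Reporting System (FAERS) are free text:
the same product appears as `TIMOLOL`, `timolol 0.5% (eye drops)`,
`TIMOLOLUM`, a brand name, or a misspelling, which makes FAERS hard to use
directly in pharmacovigilance studies.  `faersmapr` standardises FAERS drug
records in two stages:

1. **Drug-concept mapping.**  Each record is pushed through a six-step
   stop-on-first-success cascade against an offline vocabulary
   (RxNorm-style concepts with preferred terms and synonyms):

   | step | resource |
   |------|----------|
   | 1 | `drugname` vs preferred terms + synonyms, iterating progressively cleaned variants (trailing dots, special characters/parentheticals, dosages, routes) |
   | 2 | active ingredients (`prod_ai`), with multi-ingredient splitting |
   | 3 | brand registry (Article-57-like brand → ingredient) |
   | 4 | NDA number (`nda_num`, Orange-Book-like) |
   | 5 | word splitting: per-token lookup (multi-ingredient > ingredient > brand) |
   | 6 | custom verbatim mapping list |

   All matching is exact on a canonical form (case, word order, diacritics,
   abbreviations and UK/US spelling neutralised) — there is deliberately no
   edit-distance rescue, so misspellings like `cardiazem` (for `cardizem`)
   stay unmapped.  Matched concepts of any term type are *rolled up* to a
   single ingredient or a multiple-ingredients concept; an option expands
   combinations into their constituent ingredients.

2. **ATC resolution.**  One active ingredient can hold several ATC level-5
   codes depending on therapeutic use — typically split by route (oral
   timolol `C07AA06` vs ophthalmic `S01ED01`) or strength (low-dose
   finasteride `D11AX10` vs high-dose `G04CB01`).  The record's `route`,
   `dose_amt`, `dose_unit` and `dose_form` fields are parsed into evidence,
   the ingredient's crosswalk candidates are filtered by that evidence, and
   a code is assigned only when **exactly one** candidate survives;
   otherwise the pipeline abstains rather than guess.

Coverage is reported at record level and at unique-record level, where a
unique record is the 7-tuple (`drugname`, `prod_ai`, `route`, `dose_amt`,
`dose_form`, `dose_unit`, `nda_num`) compared byte-exact with missing equal
only to missing.

The package also ships a synthetic fixture generator
(`generate_vocabulary()`, `generate_faers_file()`) that emits toy
vocabularies, registries, crosswalks and FAERS drug files with planted
ground truth, so the whole pipeline is testable offline with no licensed
vocabulary downloads.

## Worked example

```r
library(faersmapr)

vocab <- generate_vocabulary("vocab", n_extra = 10, seed = 42)
gen   <- generate_faers_file("drug.txt", 500, vocab, seed = 43)
res   <- run_pipeline("drug.txt", "vocab", "out")
print(res$stats)
#> Coverage
#>   records: 500 total, 477 (95.4%) mapped to drug concepts, 355 (71.0%) to ATC
#>   unique:  399 total, 381 (95.5%) mapped to drug concepts, 285 (71.4%) to ATC
#>   per step: NAME_MATCH=328 ACTIVE_INGREDIENT=42 BRAND_REGISTRY=39 NDA=27 WORD_SPLIT=22 CUSTOM=19
```

477 of 500 records found an ingredient-level concept (the rest are planted
misspellings), and 355 additionally resolved to a single ATC code — the gap
is records whose evidence cannot disambiguate between candidate codes, so
the pipeline abstains.  A single record shows the audit trail:

```r
r <- map_record(list(drugname = "TIMOLOL 0.5% (EYE DROPS)", prod_ai = NA,
                     route = "OPHTHALMIC", dose_amt = NA, dose_form = NA,
                     dose_unit = NA, nda_num = NA),
                load_vocab("vocab"))
print(r)
#> <mapping_result> NAME_MATCH (step 1)
#>   final concepts: 1001
#>   ATC: S01ED01
cat(r$notes, sep = "\n")
#> step1: matched 'TIMOLOL' (stage DOSAGE) to concept 1001
#> atc: resolved S01ED01
```

The raw name failed as-is, matched once the parenthetical and the dosage
token were cleaned away, rolled up to the timolol ingredient (concept 1001),
and the ophthalmic route singled out `S01ED01` from timolol's two candidate
codes.

A thin command-line front end is installed with the package
(`system.file("scripts", "faersmap", package = "faersmapr")`) with
subcommands `gen`, `map` and `report`.

## Package layout

- `R/` — parsing (`parse_drug_file`), vocabulary indexing (`load_vocab`),
  name normalisation (`clean_cascade`, `canonical_form`), the cascade
  (`map_record`, `map_records`), roll-up (`roll_up`, `expand_ingredients`),
  ATC resolution (`derive_components`, `resolve_atc`), fixtures and
  reporting.
- `inst/extdata/` — the shipped, overridable lexicons: dosage units, route
  tokens and classes, route-specific dose forms, abbreviations, UK/US
  spelling variants, word-split stopwords.
- `vignettes/drug-standardization.Rmd` — the methods vignette: model,
  assumptions, parameters, design decisions and limitations.
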