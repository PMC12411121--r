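Package: faersmapr
Title: Standardise FAERS Drug Records to Ingredient Concepts and ATC Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps free-text drug records from FDA Adverse Event Reporting System
    (FAERS) DRUG files to standard ingredient-level drug concepts (RxNorm-style)
    through a six-step stop-on-first-success matching cascade over progressively
    cleaned name variants, preferred terms and synonyms, active-ingredient fields,
    a brand-name registry, New Drug Application numbers, word splitting, and a
    custom mapping list. Matched concepts of any term type are rolled up to single
    or multiple ingredients, and each record is then resolved to a single
    Anatomical Therapeutic Chemical (ATC) code using ingredient, route, strength
    and dose-form evidence, abstaining when the evidence cannot single out one
    code. Includes a synthetic fixture generator that emits toy vocabularies,
    crosswalks and FAERS drug files with planted ground truth, so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
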