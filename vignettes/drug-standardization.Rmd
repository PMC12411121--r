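---
title: "Standardising FAERS drug records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardising FAERS drug records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersmapr)
```

## The problem

Spontaneous-reporting systems such as FAERS record suspected adverse drug
reactions with free-text drug names.  The same product surfaces as a
preferred ingredient name, a synonym, a brand name, a misspelling, or any of
these decorated with dosage fragments, routes of administration,
parentheticals and stray punctuation.  Pharmacovigilance analyses need two
standardised views of each record: an ingredient-level drug concept
(RxNorm-style), and an ATC level-5 code, which encodes therapeutic use and
is the lingua franca of European drug-utilisation studies.

The second step is harder than it looks because ATC is a *use*
classification: one ingredient can legitimately hold several codes.  Timolol
taken orally for cardiovascular indications is `C07AA06`; the same molecule
in eye drops for glaucoma is `S01ED01`.  Finasteride at low dose treats
male-pattern baldness (`D11AX10`); at high dose, benign prostatic
hypertrophy (`G04CB01`).  Assigning a single code therefore requires route
and strength evidence from the record itself, and an honest system must
abstain when that evidence is insufficient.

## The mapping cascade

`map_record()` attempts six steps in a fixed order and stops at the first
success; failure of all six is a result state (`UNMAPPED`), not an error.

1. **Name match.**  The cleaning cascade (`clean_cascade()`) produces up to
   five progressively cleaned variants of `drugname`: the trimmed raw
   string; trailing spaces/dots removed; special characters and whole
   parentheticals removed; dosage tokens removed; route/dose-form tokens
   removed.  Variants are tried least-destructive-first so the most faithful
   reading of the name wins, and each is looked up against preferred terms
   *and* synonyms via the canonical form (below).
2. **Active ingredients.**  `prod_ai` is split on the FAERS conventions
   (`\` or `;`), each part matched like step 1.  If two or more parts map,
   the combination is re-aggregated to the multiple-ingredients concept with
   exactly that ingredient set when one exists.  If only some parts map, the
   record is mapped to the resolvable set and flagged `partial` in the audit
   trail — partial behaviour is explicit, never silent.
3. **Brand registry.**  The cleaned variants are looked up in the
   brand-to-ingredient registry; the registered ingredient name is then
   resolved by canonical-form lookup.  The registry lookup iterates the same
   cleaning variants as step 1 because FAERS brand strings carry the same
   dosage/route noise as any other drug name.
4. **NDA number.**  `nda_num` is normalized (digits only, leading zeros
   stripped) and resolved through the application-number table, then the
   ingredient name through the vocabulary.
5. **Word splitting.**  The fully cleaned name is tokenised; each token of
   at least 3 characters that is not a stopword is looked up against
   multi-ingredient, single-ingredient and brand-name concepts, in that
   priority per token, and the hits are unioned.  The union-plus-priority
   rule is a design choice: no minimum fraction of matching tokens is
   required, which favours recall on strings like `UNKNOWNBRAND ASPIRIN
   KIT`.
6. **Custom list.**  A verbatim (case-insensitive, trimmed) lookup in a
   user-supplied mapping list.  No cleaning variants are applied — the list
   exists precisely for strings the generic machinery cannot handle, so its
   keys must match exactly.

Two intra-step rules resolve what a bare step ordering leaves open.  When a
name hits several concepts, the tie-break prefers standard concepts, then
the standard drug vocabulary over the extension, then term types closer to
ingredient level (ingredient > multi-ingredient > brand > others), then the
lowest concept id — deterministic output, biased toward ingredient-level
results.  And a step whose best hits all roll up to the empty set (for
example a record whose name is just a dose form) is treated as *failed* and
the cascade continues: this preserves the invariant that a mapped record
always has ingredient-level concepts, and implements the guard against
mapping dose forms to drugs.

### Canonical form

All name indexes are keyed on `canonical_form()`: lowercase, diacritics
folded, punctuation collapsed, known abbreviations expanded
(`hcl` → `hydrochloride`), UK spellings unified to US
(`sulphasalazine` → `sulfasalazine`), tokens sorted lexicographically.
Token sorting makes matching invariant under word order, so
`Acetaminophen 500 MG Oral Tablet` and `oral tablet acetaminophen 500 mg`
collide by construction.  The function is idempotent, which the test suite
checks on 10,000 random strings.  There is deliberately *no* fuzzy
matching: edit-distance rescue would trade silent false positives for the
visible false negatives (misspellings) that the audit trail already
surfaces, so misspelled names such as `cardiazem` stay unmapped.

The abbreviation table, spelling table, dosage-unit list, route lexicons and
stopword list are plain-text files under `inst/extdata/`, overridable via
`normalizer_lexicons(dir = ...)`.  Their exact contents are this package's
choice and are versioned in-repo so behaviour is inspectable; an external
normalisation service could be substituted by regenerating the canonical
index, but the package itself is fully offline.

## Roll-up

`roll_up()` converts any matched concept to one of two final term types:
single ingredient or multiple ingredients.  Ingredients and
multiple-ingredient concepts are fixed points; brands follow their
ingredient relations, or — when no direct relation exists — traverse to
their branded products first (depth-capped at 3, so the brand path always
terminates at ingredients rather than drug forms); clinical drugs and drug
forms follow ingredient relations, re-aggregating multi-ingredient sets to
the combination concept (lowest id on ties); dose forms roll up to nothing.
Cycles in the relationship table are a fixture-integrity error and are
reported by name.  `expand_ingredients()` optionally replaces a combination
by its constituents in the reported final set.

## ATC resolution

`derive_components()` extracts four pieces of evidence: the ingredient set
(from the rolled-up mapping), strength (numeric `dose_amt` + `dose_unit`,
mass units normalised to mg), the dose-form concept, and a route class from
a shipped lexicon over the `route` field.  Unparseable evidence degrades to
"unknown" and is noted, never raised.  When `route` is missing but the dose
form is route-specific (an ophthalmic solution implies the ophthalmic
route), the route class is inferred from the form and flagged in the
diagnostics; an explicit route is never overridden.

`resolve_atc()` then takes the crosswalk entries keyed by the rolled-up
concept ids — the single ingredient, or the combination concept for
multi-ingredient records, so combinations resolve *only* through explicit
combination entries and "multiple ingredients in an unknown combination"
abstains by construction.  Candidates are filtered by route class (`ANY`
always survives; an unknown record route filters nothing) and by strength
range where the entry constrains it (compared in mg with a ±1% relative
tolerance to absorb unit rounding; the crosswalk bands themselves are built
with a deliberate gap so no realistic dose sits on a boundary).  Exactly one
survivor yields its code; zero or several yield abstention.  Unspecific
single-word terms (calcium-like records) need no special-case list: they
simply present many candidates and no disambiguating evidence, so the same
rule abstains.  Note that ATC resolution keys on the *pre-expansion*
rolled-up ids; the ingredient-expansion option only changes the reported
final concept set, since expansion would destroy the combination key.

`refine_to_clinical_drug()` additionally reports the most detailed
drug-level concept the evidence supports (clinical drug by
ingredient+strength, else clinical drug form by ingredient+dose form); it
enriches the audit trail but does not override the ingredient-keyed
crosswalk, which is authoritative for the code.

## Record identity and coverage

A unique drug record is the 7-tuple of `drugname`, `prod_ai`, `route`,
`dose_amt`, `dose_form`, `dose_unit`, `nda_num`, compared byte-exact on the
raw field values with missing equal only to missing.  Values are *not*
trimmed before comparison — identity is defined on the FAERS fields, not on
cleaned values — which may slightly inflate unique-record counts relative
to a trimming definition.  Empty cells, whitespace-only cells and the
literal token `NULL` all parse to the missing sentinel (`NA`), never the
empty string.  Coverage percentages are reported at one decimal, at record
level (weighted by key multiplicity) and at unique-record level; ATC
coverage can never exceed concept coverage because resolution requires a
prior mapping.

## The synthetic fixture generator

`generate_vocabulary()` emits a referentially intact toy vocabulary whose
fixed core always contains the route-split and strength-split ambiguity
cases (timolol- and finasteride-like), a brand whose correct spelling is
indexed while a transposition is not, a combination with a crosswalk entry
and one without, an ingredient absent from the crosswalk, and an
unspecific ingredient with two indistinguishable codes; `n_extra` further
ingredients get generated names, synonyms, registry brands, NDA numbers and
custom entries on a deterministic schedule.  Alongside the tables it writes
a *ledger* of every plantable name with its intended concept and cascade
step, and an *evidence plan* enumerating, per ingredient-level concept, the
route/strength/dose-form evidence options and the ATC outcome each implies.

`generate_faers_file()` samples records from the ledger according to
`noise_spec()` and perturbs the drug names with operations that are
invertible by the cleaning cascade (case change, dosage suffix, route
suffix, parenthetical, trailing punctuation); custom-list records only
receive case noise because custom matching is verbatim.  Misspellings are
single-character transpositions verified absent from every indexed name
(regenerated on collision), so their UNMAPPED expectation is sound.  The
expected outcome of every record — matched step, rolled-up concepts, ATC
code or abstention — is derived from the planting itself, before the
pipeline runs, and written to a separate ground-truth file.  The central
test property is that the pipeline agrees with this ground truth on 100% of
records across seeds.

The default `noise_spec()` is the package's standard study condition: about
5% planted-unmappable misspellings (yielding ~95% concept coverage, the
regime a curated FAERS mapping operates in), 10% records mappable only
through `prod_ai`, 5% through NDA numbers, smaller shares for the custom
list and word splitting, and 30% of records with their disambiguating
evidence withheld (producing ~70–75% ATC coverage through abstention).
These values were fixed once, as a realistic mixture, and are not tuned.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: true vocabulary scale (tens of invented ingredients
vs hundreds of thousands of concepts), real misspelling distributions
(human typos are not uniform transpositions), reporting-frequency skew
(blockbuster drugs dominate real FAERS), multi-language names, and the
semantic correctness of a production crosswalk.  The tests establish that
the *mechanism* is exact: every rule fires when and only when it should.

## Numerical and procedural choices

- Test corpora use 500–1,100 records across five seed pairs, and the
  acceptance script 2,000 records; these sizes exercise every channel of
  the generator many times over while keeping a full run in tens of
  seconds.
- Strength tolerance ±1% relative, in mg.  Unit conversions cover
  mg/g/mcg/ug/kg; non-mass evidence (mL, %) never disqualifies a candidate.
- Determinism: vocabulary indexing is input-order-independent (sorted
  within each key), tie-breaks end at the lowest concept id, and the
  generator restores the caller's RNG state.
- Degenerate inputs: empty files produce valid zero reports; malformed
  lines are skipped with their line numbers reported; lookup of anything
  in an empty table returns the empty result, not an error.

## Limitations

The cascade is exact-match by design, so genuinely novel misspellings stay
unmapped until added to the custom list.  Combination products resolve to
ATC only through explicit combination entries.  Level 1–4 ATC codes are
never assigned when level-5 resolution fails — abstention is preferred over
coarse codes.  The shipped lexicons are starting points, not exhaustive:
production use would extend the route lexicon and abbreviation table to the
local data's idiom.
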