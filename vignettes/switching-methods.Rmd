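---
title: "Formulary switching: model, knowledge bases and the synthetic study cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formulary switching: model, knowledge bases and the synthetic study cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchrx)
```

## The procedure

At hospital admission each outpatient medication is mapped onto the closed
hospital formulary. `switchrx` models this as a strict decision cascade per
reconciled medication. Information gates run first, in fixed order:
`NOT_PRESCRIBED`, `SELF_MEDICATION`, `MISSING_PRODUCT`, `MISSING_STRENGTH`;
the first hit terminates the medication, because the cascade needs the
active ingredients, the product name, the strengths and the dosage form.
Eligible medications then pass through six steps, the first match winning:

* **S0** — the identical product (name, component multiset, dosage-form
  class) is stocked; no switch.
* **S1** — an ingredient is on the substitution-exclusion list of
  narrow-therapeutic-index drugs; switching is not allowed and the original
  product is ordered on special request. We evaluate S0 *before* S1: if the
  patient's exact product is stocked no switch occurs, so the risk the
  exclusion list guards against never arises. The cascade order inside a
  graphical algorithm is otherwise ambiguous in prose; this ordering is our
  documented convention.
* **S2** — *aut idem* generic switching: a stocked product carries exactly
  the same components at exactly the same normalized doses in the same
  dosage-form class.
* **S3** — *aut simile* therapeutically equivalent switching, only when an
  explicit dose-equivalence entry exists for exactly the medication's
  ingredients and doses, and only within the ATC level stated on the entry
  (level 5 = same substance, level 4 = same chemical subgroup, e.g.
  simvastatin → rosuvastatin in `C10AA`, omeprazole → pantoprazole in
  `A02BC`).
* **S4** — a patient-individual switch entered by a pharmacist as an
  override record. The engine never promotes itself to S4; pharmacist
  judgment is an input, not an inference.
* **S5** — nothing applies; the original product is ordered from the
  wholesaler. This is the expensive outcome the algorithm minimizes.

Every medication receives exactly one terminal status, so status counts
always partition the cohort.

### Ingredient, strength and form identity

Ingredient identity is `(normalized name, salt)`: metoprolol succinate and
tartrate are different switching entities (they resolve differently in the
cascade), while a synonym map (salbutamol ↔ albuterol, dipyrone ↔
metamizole, ...) folds alternate names. Strengths compare only after unit
normalization (masses to mg, mass/volume to mg/ml); international units are
a separate dimension and never compare with masses. Equality is exact — no
tolerance window, since dose rounding is never part of the procedure.
Dosage forms compare by configurable equivalence classes; the packaged
default is exact form-token equality, the most conservative choice.
Interaction and PIM screening, by contrast, operate on the ingredient name
only (salt-agnostic): those properties belong to the active moiety.

### Combination products

A combination product (≥ 2 components) is one switch. Resolution prefers a
stocked equivalent combination (combo→combo generic); otherwise full
decomposition is attempted: *every* component must be available as a
stocked mono-product at the exact strength and form class — all or nothing.
A partial decomposition falls through to S3/S4/S5. Equivalence entries
accept component multisets on either side (normally of length one), so a
combination can also map to a single equivalent product; the ATC-agreement
assertion is only applicable to single-ingredient entries, since a
combination ATC code never shares level 4 with a mono substance.

### Review before switching

Drug–drug interaction screening enumerates all unordered concomitant
ingredient pairs (combination components included; medications not
prescribed during the stay excluded) and intersects them with the
interaction table. Patients with fewer than two concomitant medications are
not assessable and are excluded from the denominator. PIM screening applies
an age gate (default 65 years) and flags PRISCUS membership or FORTA
category C/D, one finding per distinct ingredient. One interaction "count"
is one unique ingredient pair per patient; an operational definition the
source material leaves open, recorded here as the package convention.
Review findings are reported, never auto-applied.

### Reconciliation

Per-patient records from the three sources (pharmacist interview,
brought-in medication lists, medical documents) merge by medication
identity — product name first, ingredient multiset as fallback for unnamed
records. Each field is filled from the highest-priority source that
provides it, with per-field provenance; the default priority is interview >
medication list > documents, reflecting that the interview is typically the
richest source. Conflicting non-missing strengths raise a conflict flag and
are never silently overridden — a patient-safety decision. A patient's
"main information source" is the source contributing the most filled
fields, ties resolved by priority; this adjudication rule is likewise a
package convention.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| source priority | interview > list > documents | reconciliation fill order |
| `age_threshold` | 65 years | PIM age gate |
| form classes | exact token equality | dosage-form equivalence |
| exclusion list | 7 narrow-therapeutic-index drugs | S1 membership |
| equivalence tables | PPI / statin / basal-insulin entries | S3 options |
| percentage rounding | one decimal, half up | reporting convention |

Quartiles use the linear-interpolation order-statistic rule ("type 7",
`stats::quantile`'s default) throughout; the source statistics do not state
their quantile convention, so one had to be fixed, and the packaged cohort
is constructed to satisfy the published quartiles under it.

## The synthetic study cohort

`build_paper_fixture()` deterministically constructs 100 patients with 475
medications (511 active ingredients — the 23 combination products carry 36
extra components) and a matched knowledge base. The construction is
attribute-driven: a record destined to be "generic-switchable" simply has a
product name absent from the formulary while a stocked product carries the
same components — the label S2 exists nowhere in the fixture and is
re-derived by the engine. `verify_fixture_marginals()` re-runs the whole
pipeline and asserts every aggregate (status counts, per-drug splits of the
frequency top list, combination sub-analysis, demographics, review rates);
`build_paper_fixture()` refuses to return a non-conforming construction.

Design choices worth knowing:

* **Interaction wiring.** The interaction table holds three pairs
  (ASA–amlodipine, omeprazole–clopidogrel, ramipril–allopurinol); 15 + 7 +
  9 = 31 designated patients carry exactly one pair each and placement
  guarantees no accidental co-occurrence elsewhere, giving ASA and
  amlodipine 15 findings each. The packaged interaction and PRISCUS/FORTA
  tables are small synthetic illustrative sets, not clinical references;
  real deployments load their own via `kb_load()`.
* **Combination sub-analysis.** The 23 combinations resolve as 4 S0, 12 S2
  (1 combo→combo + 11 full decompositions), 1 S3 (combo → equivalent
  mono), 1 S4 (override → mono), 4 S5 and 1 with unknown product name.
  "Resolved to a mono-product" = 11 + 1 + 1 = 13; "resolved as a
  combination product" = the 4 stocked combos + 1 combo→combo switch + the
  4 wholesaler orders of the original combination = 9. The published
  counts for this sub-analysis cannot all be pairwise disjoint (22
  "switched" products vs 14 actively switched by step); this reading
  satisfies the step counts and the 13-vs-9 split simultaneously and is
  the package's documented resolution of that ambiguity.
* **Frequency top list.** Named rows are realized as mono records; one row
  (bisoprolol, 12 records) is under-specified by 3 in its printed
  breakdown, and the fixture assigns the remainder to `NOT_PRESCRIBED`.
  Combinations containing a named ingredient do not count toward its row.
* **Percentage arithmetic.** Two published percentages are inconsistent
  with their own counts (200/475 = 42.1%, not 42.0; 114/475 = 24.0%, not
  23.9). The fixture realizes the exact counts, and all reported
  percentages are computed from them.
* **Unnamed filler records** use real but unremarkable drug names with
  realistic attributes; product names are synthetic (`... HSP` for stocked,
  `... EXT` for outpatient products).

`generate_cohort()` is the stochastic counterpart for property testing: a
seeded generator whose sequential conditional probabilities (not
prescribed → missing product → missing strength → excluded → stocked →
generic → equivalent → wholesaler) default to the study rates, and whose
knowledge base is generated alongside the cohort so that every category is
again realized structurally. Its calibration is tested at roughly 10,000
medications against 3-sigma binomial bounds.

### What passing tests do and do not show

The fixture demonstrates that the engine reproduces the published
aggregates when the knowledge bases encode exactly the published switching
opportunities. It does not exercise free-text medication entries, brand
name ambiguity, multi-strength regimens, dose-schedule conversion between
equivalents (explicitly out of scope), severity grading of interactions, or
a formulary at realistic scale (~60 products vs thousands). Conclusions
about real reconciliation data quality therefore do not follow from green
tests; the engine's correctness properties (cascade order, exhaustiveness,
content conservation under S2, determinism) do.

## Numerical and degenerate-input choices

Candidate ordering is lexicographic by product name — a deterministic
tie-break; all candidates are retained in the decision rationale. Empty
formularies, empty tables and empty cohorts are valid inputs yielding empty
results (every eligible non-excluded medication then lands in S5).
Percentages round half up to one decimal. Reports are pure functions of
their inputs; identical inputs give byte-identical artifacts. Problem sizes
in the test suite — 1,000 random medications for the cascade properties,
formularies up to 100 products for the brute-force equivalence checks,
~10,000 medications for generator calibration — were chosen as the package's
own verification scale.

## Known limitations

* The equivalence tables ship only the entries needed by the packaged
  cohort; licensed compendia must be supplied by the user.
* Interaction severity is carried through but not interpreted; no
  dose-dependent or renal logic.
* Discharge-direction switching (formulary → outpatient) is not modeled.
* The "main source" and "one DDI = one unique pair" conventions are
  package decisions where the underlying procedure is unspecified.
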