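# switchrx

Switching outpatient medications to a hospital formulary, the admission-side
workhorse of a hospital pharmacy, as a reproducible rules engine.

## The problem

In healthcare systems with strictly separated outpatient and inpatient
sectors, a hospital pharmacy may only dispense products on its own (short)
formulary. At admission, every outpatient medication must therefore be
mapped onto a stocked product — or ordered individually from a wholesaler at
much higher cost. In routine care this mapping is done ad hoc on the ward.
`switchrx` implements the standardized alternative: a strict six-step
cascade applied per medication after information gates and a pre-switch
medication review.

**Gates** (first hit wins): `NOT_PRESCRIBED` (drug paused or stopped for the
stay), `SELF_MEDICATION` (not transferred), `MISSING_PRODUCT` /
`MISSING_STRENGTH` (reconciliation could not establish the product name or
dose — the algorithm cannot run).

**Cascade** (first matching step wins):

| Step | Rule | Order channel |
|------|------|---------------|
| S0 | the exact product (name + strengths + dosage form) is stocked — no switch | pharmacy stock |
| S1 | an ingredient is on the substitution-exclusion list (carbamazepine, phenobarbital, phenytoin, primidone, valproic acid, ciclosporin, tacrolimus) — switching not allowed | special request |
| S2 | *aut idem*: a stocked product has the identical component multiset (ingredient + salt + normalized dose) and dosage-form class; combination products resolve combo→combo first, else by all-or-nothing decomposition into stocked mono-products (counted as one switch) | stock |
| S3 | *aut simile*: an explicit dose-equivalence table entry (within ATC level 4/5) maps the medication to a stocked equivalent at a defined dose | stock |
| S4 | patient-individual switch entered by a pharmacist (an override; never auto-derived) | stock |
| S5 | nothing applies — wholesaler order | wholesaler |

The pre-switch review screens all concomitant ingredient pairs against an
interaction table (patients with ≥ 2 medications prescribed during the stay
are assessable) and, for patients aged ≥ 65, flags PRISCUS-listed or FORTA
C/D ingredients as potentially inappropriate medication.

## Worked example

```r
library(switchrx)
kb <- kb_load(system.file("extdata", "kb", package = "switchrx"))
med <- merge_sources(source_records(data.frame(
  patient_id = "P001", source = "interview",
  product_name = "Omep 20 EXT", ingredients = "omeprazole:20 mg",
  dosage_form = "tablet", atc = "A02BC01")))
classify_switch(med, kb)
#> $status     : "S3"
#> $targets    : "Pantoprazole 40mg HSP"
#> $channel    : "stock"
#> $resolution : "mono"
#> $rationale  : "equivalence table 'ppi' (ATC level 4): Pantoprazole 40mg HSP"
```

No omeprazole product is stocked and no generic exists (S0 and S2 fail), but
the packaged PPI equivalence table maps omeprazole 20 mg to pantoprazole
40 mg — a therapeutically equivalent switch within ATC level 4 (`A02BC`), so
the medication is ordered from pharmacy stock as S3.

Running the whole packaged study cohort end to end:

```r
fx  <- build_paper_fixture()                 # 100 patients, 475 medications
coh <- reconcile(fx$sources, fx$patients)
rev <- review_report(coh, fx$kb)
dec <- switch_cohort(coh, fx$kb, fx$overrides)
summarize_pipeline(dec, coh, rev)
#> <summary_report> 475 medications in 100 patients (median 4 per patient)
#>   S0                 88  ( 18.5%)
#>   S1                  1  (  0.2%)
#>   S2                200  ( 42.1%)
#>   S3                  8  (  1.7%)
#>   S4                  2  (  0.4%)
#>   S5                 39  (  8.2%)
#>   NOT_PRESCRIBED     15  (  3.2%)
#>   MISSING_PRODUCT   114  ( 24.0%)
#>   MISSING_STRENGTH    8  (  1.7%)
#>   DDI 31/79 patients (39%); PIM 12/73 aged 65+ (16%)
```

Of 475 medications, 88 were already stocked, 200 could be switched
generically, 8 via equivalence tables, 2 individually by a pharmacist; 39
needed wholesaler orders; 137 could not enter the cascade for lack of
information or because they were not prescribed during the stay.
`run_pipeline()` does all of the above from CSV inputs and writes
`decisions.csv`, `orders.csv`, `review_findings.csv`, `summary.json` and
`summary.md`; `inst/cli/switchrx` is a thin shell wrapper around it.

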