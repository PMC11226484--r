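Package: switchrx
Title: Algorithmic Switching of Outpatient Medications to a Hospital Formulary
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A rules engine for converting a reconciled outpatient medication
    list into hospital-formulary orders at admission. Implements a six-step
    switching cascade (S0 no switch required, S1 substitution-exclusion,
    S2 generic "aut idem" switching, S3 therapeutically equivalent "aut simile"
    switching via dose-equivalence tables within the ATC hierarchy, S4
    pharmacist override, S5 wholesaler order), preceded by information gates
    and a pre-switch medication review (pairwise drug-drug interaction
    screening and PRISCUS/FORTA screening for potentially inappropriate
    medication in older adults). Ships a deterministic synthetic study cohort
    of 100 patients with 475 medications whose attribute flags reproduce a
    published evaluation's aggregate statistics, a seeded stochastic cohort
    generator for property testing, knowledge-base loaders with schema
    validation, and end-to-end pipeline reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
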