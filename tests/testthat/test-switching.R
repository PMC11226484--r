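test_that("gates fire in strict precedence order", {
  meds <- rbind(
    as_med_row(product_name = "Chemo EXT", ingredients = "capecitabine:500 mg",
               prescribed = FALSE),
    as_med_row(product_name = NA, ingredients = "unknown:10 mg",
               prescribed = FALSE),               # not prescribed beats missing
    as_med_row(product_name = NA, ingredients = "unknown2:10 mg"),
    as_med_row(product_name = "K EXT", ingredients = "known:NA"),
    as_med_row(product_name = "S EXT", ingredients = "selfdrug:10 mg",
               selfmed = TRUE),
    as_med_row(product_name = "OK EXT", ingredients = "okdrug:10 mg"))
  expect_equal(gate(meds),
               c("NOT_PRESCRIBED", "NOT_PRESCRIBED", "MISSING_PRODUCT",
                 "MISSING_STRENGTH", "SELF_MEDICATION", "ELIGIBLE"))
})

test_that("the cascade reproduces the canonical step examples", {
  kb <- paper_kb()
  ov <- build_paper_fixture(verify = FALSE)$overrides
  cases <- list(
    list(med = as_med_row(patient_id = "P001", product_name = "Apixaban 5mg HSP",
                          ingredients = "apixaban:5 mg"), status = "S0"),
    list(med = as_med_row(patient_id = "P001", product_name = "Carbamazepin ret EXT",
                          ingredients = "carbamazepine:200 mg",
                          dosage_form = "retard-tablet"), status = "S1"),
    list(med = as_med_row(patient_id = "P001", product_name = "ASS Dura EXT",
                          ingredients = "acetylsalicylic acid:100 mg"), status = "S2"),
    list(med = as_med_row(patient_id = "P001", product_name = "Omep EXT",
                          ingredients = "omeprazole:20 mg", atc = "A02BC01"),
         status = "S3", target = "Pantoprazole 40mg HSP"),
    list(med = as_med_row(patient_id = "P001", product_name = "Metotart EXT",
                          ingredients = "metoprolol|tartrate:50 mg"), status = "S5"),
    list(med = as_med_row(patient_id = "P001", product_name = "Actos EXT",
                          ingredients = "pioglitazone:30 mg", atc = "A10BG03"),
         status = "S5"),
    list(med = as_med_row(patient_id = "P092", product_name = "Omeprazole 40mg EXT",
                          ingredients = "omeprazole:40 mg", atc = "A02BC01"),
         status = "S4", target = "Pantoprazole 40mg HSP"))
  for (cs in cases) {
    d <- classify_switch(cs$med, kb, ov)
    expect_equal(d$status, cs$status, label = cs$med$product_name)
    if (!is.null(cs$target)) expect_equal(d$targets, cs$target)
    expect_equal(d$channel,
                 c(S0 = "stock", S1 = "special_request", S2 = "stock",
                   S3 = "stock", S4 = "stock", S5 = "wholesaler")[[cs$status]])
  }
})

test_that("combination products resolve combo-first, then all-or-nothing", {
  prods <- data.frame(
    product_name = c("CandHCT HSP", "Cand 16 HSP", "HCT 12.5 HSP", "Eze 10 HSP"),
    dosage_form = "tablet", atc = NA_character_,
    components = c("candesartan:16 mg;hydrochlorothiazide:12.5 mg",
                   "candesartan:16 mg", "hydrochlorothiazide:12.5 mg",
                   "ezetimibe:10 mg"),
    stringsAsFactors = FALSE)
  kb <- kb_of(prods)
  combo <- as_med_row(product_name = "CandHCT EXT",
                      ingredients = "candesartan:16 mg;hydrochlorothiazide:12.5 mg")
  d <- decompose_combination(combo, kb)
  expect_equal(d$mode, "combination")        # combo->combo preferred
  expect_equal(d$targets, "CandHCT HSP")
  ezesim <- as_med_row(product_name = "EzeSim EXT",
                       ingredients = "ezetimibe:10 mg;simvastatin:40 mg")
  expect_equal(decompose_combination(ezesim, kb)$mode, "none")  # partial fails
  kb2 <- kb_of(rbind(prods, data.frame(
    product_name = "Simva 40 HSP", dosage_form = "tablet", atc = NA,
    components = "simvastatin:40 mg", stringsAsFactors = FALSE)))
  d2 <- decompose_combination(ezesim, kb2)
  expect_equal(d2$mode, "decomposition")
  expect_setequal(d2$targets, c("Eze 10 HSP", "Simva 40 HSP"))
  # one switch, multiple targets, content conserved
  dec <- classify_switch(ezesim, kb2)
  expect_equal(dec$status, "S2")
  expect_equal(length(dec$targets), 2)
})

test_that("an override with a target outside the formulary is an error", {
  kb <- kb_of(empty_products())
  ov <- data.frame(patient_id = "T1", medication = "X EXT",
                   target_product = "Ghost HSP", note = "",
                   stringsAsFactors = FALSE)
  med <- as_med_row(product_name = "X EXT", ingredients = "x:1 mg")
  expect_error(classify_switch(med, kb, ov), "not in the formulary")
})

test_that("cascade equals the brute-force lowest-index predicate evaluator", {
  set.seed(2024)
  excl <- default_exclusion_list()$ingredient
  n_checked <- 0L
  for (rep in 1:60) {
    cs <- random_case(n_products = sample(3:40, 1),
                      ing_pool = c(sprintf("ing%02d", 1:10), "carbamazepine"))
    eq <- if (stats::runif(1) < 0.4) data.frame(
      table_id = "t", source_ingredient = "ing01", source_strength = "10 mg",
      target_ingredient = "ing02", target_strength = "20 mg",
      match_level = 4L, stringsAsFactors = FALSE) else NULL
    ov_meds <- if (stats::runif(1) < 0.3) cs$med_name else character()
    kb <- kb_of(cs$products, exclusion = default_exclusion_list(),
                equivalence = eq)
    ov <- if (length(ov_meds)) data.frame(
      patient_id = "T1", medication = ov_meds,
      target_product = cs$products$product_name[1],
      note = "", stringsAsFactors = FALSE) else NULL
    med <- as_med_row(product_name = cs$med_name, ingredients = cs$med_spec,
                      dosage_form = cs$med_form)
    got <- classify_switch(med, kb, ov)$status
    want <- oracle_cascade(med, cs$products, excl, eq, ov_meds)
    expect_equal(got, want, label = sprintf("case %d", rep))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 60L)
})

test_that("statuses are exhaustive/exclusive and S2 conserves content", {
  fx <- build_paper_fixture(verify = FALSE)
  coh <- reconcile(fx$sources, fx$patients)
  dec <- switch_cohort(coh, fx$kb, fx$overrides)
  expect_equal(nrow(dec), nrow(coh$medications))
  expect_true(all(dec$status %in% c("S0", "S1", "S2", "S3", "S4", "S5",
                                    "NOT_PRESCRIBED", "SELF_MEDICATION",
                                    "MISSING_PRODUCT", "MISSING_STRENGTH")))
  expect_equal(sum(table(dec$status)), nrow(coh$medications))
  # S2 conservation: target content multiset equals the source's
  fm <- fx$kb$formulary
  s2 <- which(dec$status == "S2")
  for (i in s2) {
    med <- coh$medications[coh$medications$med_id == dec$med_id[i], ]
    tg <- unlist(dec$targets[i])
    tg_sig <- switchrx:::component_signature(
      do.call(rbind, fm$comps[match(tg, fm$product_name)]))
    expect_equal(tg_sig, med$signature)
  }
  # S1 decisions carry an exclusion-listed ingredient
  s1_meds <- coh$medications[coh$medications$med_id %in% dec$med_id[dec$status == "S1"], ]
  expect_true(all(vapply(s1_meds$comps, function(cc)
    any(cc$ingredient %in% default_exclusion_list()$ingredient), logical(1))))
  # cascade monotonicity spot-check: no S5 medication has a generic candidate
  s5 <- coh$medications[coh$medications$med_id %in% dec$med_id[dec$status == "S5"], ]
  for (i in seq_len(nrow(s5)))
    if (s5$n_components[i] == 1L)
      expect_equal(nrow(find_generic_candidates(s5[i, ], fx$kb)), 0)
})

test_that("an empty formulary sends every eligible non-excluded medication to S5", {
  fx <- build_paper_fixture(verify = FALSE)
  coh <- reconcile(fx$sources, fx$patients)
  bare <- knowledge_base(formulary = formulary(empty_products()),
                         exclusion = default_exclusion_list())
  dec <- switch_cohort(coh, bare, NULL)
  elig <- gate(coh$medications) == "ELIGIBLE"
  excl <- dec$status == "S1"
  expect_true(all(dec$status[elig & !excl] == "S5"))
  expect_equal(sum(excl), 1)
})

test_that("order lists group by channel, sort and aggregate quantities", {
  prods <- data.frame(product_name = "Gen HSP", dosage_form = "tablet",
                      atc = NA, components = "g:5 mg", stringsAsFactors = FALSE)
  kb <- kb_of(prods)
  src <- do.call(rbind, lapply(c("P1", "P2"), function(p)
    data.frame(patient_id = p, source = "interview", product_name = "Gen EXT",
               ingredients = "g:5 mg", dosage_form = "tablet", atc = NA,
               administration_times = NA, prescribed_during_stay = TRUE,
               self_medication = FALSE, stringsAsFactors = FALSE)))
  coh <- reconcile(source_records(src))
  dec <- switch_cohort(coh, kb)
  ord <- build_order_list(dec)
  expect_equal(nrow(ord$orders), 1)           # aggregated across patients
  expect_equal(ord$orders$quantity, 2L)
  expect_equal(ord$orders$channel, "stock")
  # fixture: the wholesaler group holds exactly the S5 records
  fx <- build_paper_fixture(verify = FALSE)
  fcoh <- reconcile(fx$sources, fx$patients)
  fdec <- switch_cohort(fcoh, fx$kb, fx$overrides)
  ford <- build_order_list(fdec)
  ws <- ford$orders[ford$orders$channel == "wholesaler", ]
  expect_equal(sum(ws$quantity), sum(fdec$status == "S5"))
  expect_equal(nrow(ford$needs_information),
               sum(fdec$status %in% c("MISSING_PRODUCT", "MISSING_STRENGTH",
                                      "NOT_PRESCRIBED", "SELF_MEDICATION")))
  expect_false(is.unsorted(ws$product_name))
})
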