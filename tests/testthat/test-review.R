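meds_of <- function(...) do.call(rbind, list(...))

test_that("concomitant pairs enumerate distinct ingredients, combos included", {
  one <- as_med_row(product_name = "A", ingredients = "a:1 mg")
  expect_equal(nrow(concomitant_pairs(one)), 0)
  three <- meds_of(as_med_row(product_name = "A", ingredients = "a:1 mg"),
                   as_med_row(product_name = "B", ingredients = "b:1 mg"),
                   as_med_row(product_name = "C", ingredients = "c:1 mg"))
  expect_equal(nrow(concomitant_pairs(three)), choose(3, 2))
  withcombo <- rbind(three,
                     as_med_row(product_name = "D", ingredients = "d:1 mg"),
                     as_med_row(product_name = "E", ingredients = "e:1 mg;f:2 mg"))
  expect_equal(nrow(concomitant_pairs(withcombo)), choose(6, 2))
  # not-prescribed medications never contribute
  mixed <- rbind(three, as_med_row(product_name = "Z", ingredients = "z:1 mg",
                                   prescribed = FALSE))
  expect_equal(nrow(concomitant_pairs(mixed)), choose(3, 2))
})

test_that("DDI screening matches the interaction table symmetrically", {
  kb <- kb_of(empty_products(),
              interactions = data.frame(ingredient_a = "clopidogrel",
                                        ingredient_b = "omeprazole",
                                        severity = "moderate"))
  pat <- meds_of(as_med_row(product_name = "Omep", ingredients = "omeprazole:20 mg"),
                 as_med_row(product_name = "Plavix", ingredients = "clopidogrel:75 mg"))
  d <- screen_ddi(pat, kb)
  expect_true(d$assessable)
  expect_equal(nrow(d$findings), 1)
  expect_equal(sort(c(d$findings$ingredient_a, d$findings$ingredient_b)),
               c("clopidogrel", "omeprazole"))
  # single medication -> not assessable
  d1 <- screen_ddi(pat[1, ], kb)
  expect_false(d1$assessable)
  # empty table -> assessable, no findings
  d0 <- screen_ddi(pat, kb_of(empty_products()))
  expect_true(d0$assessable)
  expect_equal(nrow(d0$findings), 0)
})

test_that("DDI screening equals brute-force pair lookup on random patients", {
  set.seed(99)
  pool <- sprintf("g%02d", 1:10)
  for (rep in 1:25) {
    ings <- sample(pool, sample(2:8, 1))
    meds <- do.call(rbind, lapply(ings, function(g)
      as_med_row(product_name = paste0(g, " EXT"),
                 ingredients = paste0(g, ":10 mg"))))
    tab <- t(utils::combn(pool, 2))
    tab <- tab[stats::runif(nrow(tab)) < 0.2, , drop = FALSE]
    kb <- kb_of(empty_products(), interactions = if (nrow(tab)) data.frame(
      ingredient_a = tab[, 1], ingredient_b = tab[, 2], severity = "x",
      stringsAsFactors = FALSE) else NULL)
    got <- screen_ddi(meds, kb)$findings
    want <- 0L
    if (nrow(tab)) for (r in seq_len(nrow(tab)))
      if (all(tab[r, ] %in% ings)) want <- want + 1L
    expect_equal(nrow(got), want)
    # monotonicity: an extra medication never removes a finding
    extra <- rbind(meds, as_med_row(product_name = "extra EXT",
                                    ingredients = "extra:1 mg"))
    expect_true(nrow(screen_ddi(extra, kb)$findings) >= nrow(got))
  }
})

test_that("PIM screening applies the age gate and the FORTA C/D rule", {
  kb <- kb_of(empty_products(), pim = data.frame(
    ingredient = c("oxybutynin", "digoxin", "metformin"),
    catalog = c("priscus", "forta", "forta"),
    category = c(NA, "C", "B"), stringsAsFactors = FALSE))
  meds <- meds_of(as_med_row(product_name = "O", ingredients = "oxybutynin:5 mg"),
                  as_med_row(product_name = "D", ingredients = "digoxin:0.2 mg"),
                  as_med_row(product_name = "M", ingredients = "metformin:1000 mg"))
  expect_equal(nrow(screen_pim(60, meds, kb)), 0)     # below the gate
  f <- screen_pim(71, meds, kb)
  expect_equal(sort(f$ingredient), c("digoxin", "oxybutynin"))  # FORTA B excluded
  expect_equal(f$catalog[f$ingredient == "digoxin"], "forta")
  expect_equal(f$category[f$ingredient == "digoxin"], "C")
  only_b <- meds[3, ]
  expect_equal(nrow(screen_pim(80, only_b, kb)), 0)
})

test_that("cohort review totals equal the sum of per-patient screens", {
  g <- generate_cohort(generator_params(n_patients = 60, seed = 11,
                                        ddi_pair_density = 0.05))
  coh <- reconcile(g$sources, g$patients)
  rep_ <- review_report(coh, g$kb)
  per <- vapply(g$patients$patient_id, function(pid) {
    meds <- coh$medications[coh$medications$patient_id == pid, , drop = FALSE]
    d <- screen_ddi(meds, g$kb)
    c(assessable = d$assessable, ddi = nrow(d$findings) > 0)
  }, logical(2))
  expect_equal(rep_$n_assessable, sum(per["assessable", ]))
  expect_equal(rep_$n_with_ddi, sum(per["ddi", ]))
  expect_equal(rep_$n_patients, 60)
  # empty cohort -> all-zero summary
  empty <- reconcile(source_records(g$sources[0, ]),
                     g$patients[0, , drop = FALSE])
  r0 <- review_report(empty, g$kb)
  expect_equal(r0$n_assessable + r0$n_with_ddi + r0$n_with_pim +
                 r0$n_aged_65plus, 0)
})

test_that("most frequent interacting ingredients break ties alphabetically", {
  kb <- kb_of(empty_products(), interactions = data.frame(
    ingredient_a = c("b", "c"), ingredient_b = c("a", "a"),
    severity = "x", stringsAsFactors = FALSE))
  src <- do.call(rbind, lapply(c("a", "b", "c"), function(g)
    data.frame(patient_id = "P1", source = "interview",
               product_name = paste0(g, " EXT"),
               ingredients = paste0(g, ":1 mg"), dosage_form = "tablet",
               atc = NA, administration_times = NA,
               prescribed_during_stay = TRUE, self_medication = FALSE,
               stringsAsFactors = FALSE)))
  coh <- reconcile(source_records(src),
                   data.frame(patient_id = "P1", age = 70L,
                              department = "urology", stringsAsFactors = FALSE))
  r <- review_report(coh, kb)
  expect_equal(r$top_interacting$ingredient[1], "a")  # 2 findings
  expect_equal(r$top_interacting$ingredient[2:3], c("b", "c"))  # 1 each, alpha
})
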