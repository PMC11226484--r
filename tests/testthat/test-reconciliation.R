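src_row <- function(pid = "P1", source, product_name = NA, ingredients = NA,
                    dosage_form = NA, times = NA, prescribed = NA, selfmed = NA)
  data.frame(patient_id = pid, source = source, product_name = product_name,
             ingredients = ingredients, dosage_form = dosage_form,
             atc = NA_character_, administration_times = times,
             prescribed_during_stay = prescribed, self_medication = selfmed,
             stringsAsFactors = FALSE)

test_that("fields merge by priority with per-field provenance", {
  recs <- rbind(
    src_row(source = "interview", product_name = "Ramilich 5", ingredients = "ramipril:NA"),
    src_row(source = "medical_documents", ingredients = "ramipril:5 mg",
            dosage_form = "tablet"))
  m <- merge_sources(source_records(recs))
  expect_equal(nrow(m), 1)
  expect_equal(m$product_name, "Ramilich 5")
  expect_equal(m$comps[[1]]$qty, 5)
  expect_equal(m$provenance[[1]]$product_name, "interview")
  expect_equal(m$provenance[[1]]$strengths, "medical_documents")
  expect_equal(m$dosage_form, "tablet")
  expect_false(m$conflict)
})

test_that("a single-source record passes through unchanged", {
  recs <- src_row(source = "medication_list", product_name = "ASS 100",
                  ingredients = "acetylsalicylic acid:100 mg",
                  dosage_form = "tablet", times = "1-0-0")
  m <- merge_sources(source_records(recs))
  expect_equal(nrow(m), 1)
  expect_equal(m$product_name, "ASS 100")
  expect_equal(m$completeness, "COMPLETE")
  expect_true(m$prescribed_during_stay)   # default
  expect_false(m$self_medication)         # default
})

test_that("conflicting strengths are flagged, never silently overridden", {
  recs <- rbind(
    src_row(source = "interview", product_name = "Simva", ingredients = "simvastatin:20 mg"),
    src_row(source = "medical_documents", product_name = "Simva",
            ingredients = "simvastatin:40 mg"))
  m <- merge_sources(source_records(recs))
  expect_equal(nrow(m), 1)
  expect_true(m$conflict)
  expect_match(m$conflict_detail, "simvastatin")
  expect_equal(m$comps[[1]]$qty, 20)  # higher-priority value retained
})

test_that("merging is idempotent and loses no information", {
  set.seed(77)
  fields <- list(product_name = "Drug X", ingredients = "drugx:10 mg",
                 dosage_form = "tablet", times = "1-0-1")
  for (rep in 1:25) {
    # the ingredient multiset is always present, so the three partial views
    # are identifiable as one medication; other fields are masked at random
    rows <- lapply(c("interview", "medication_list", "medical_documents"),
                   function(s) {
                     mask <- stats::runif(4) < 0.5
                     src_row(source = s,
                             product_name = if (mask[1]) fields$product_name else NA,
                             ingredients = if (mask[2]) fields$ingredients else "drugx:NA",
                             dosage_form = if (mask[3]) fields$dosage_form else NA,
                             times = if (mask[4]) fields$times else NA)
                   })
    recs <- source_records(do.call(rbind, rows))
    m <- merge_sources(recs)
    expect_equal(nrow(m), 1)
    # brute-force field-wise argmax over priority
    for (f in c("product_name", "dosage_form")) {
      vals <- do.call(rbind, rows)[[f]]
      want <- vals[!is.na(vals)][1]  # rows already in priority order
      if (!is.na(m[[f]])) expect_equal(m[[f]], want)
      else expect_true(all(is.na(vals)))
    }
    # idempotence: re-merging the merged record reproduces it
    again <- merge_sources(source_records(data.frame(
      patient_id = "P1", source = "interview",
      product_name = m$product_name, ingredients = m$ingredients,
      dosage_form = m$dosage_form, atc = m$atc,
      administration_times = m$administration_times,
      prescribed_during_stay = m$prescribed_during_stay,
      self_medication = m$self_medication, stringsAsFactors = FALSE)))
    expect_equal(again$signature, m$signature)
    expect_equal(again$completeness, m$completeness)
  }
})

test_that("unnamed records join a named group via the ingredient multiset", {
  recs <- rbind(
    src_row(source = "interview", product_name = "Eliquis", ingredients = "apixaban:NA"),
    src_row(source = "medication_list", ingredients = "apixaban:5 mg"))
  m <- merge_sources(source_records(recs))
  expect_equal(nrow(m), 1)
  expect_equal(m$comps[[1]]$qty, 5)
})

test_that("completeness statuses partition and rank as defined", {
  meds <- rbind(
    as_med_row(product_name = NA, ingredients = "a:5 mg"),
    as_med_row(product_name = "B EXT", ingredients = "b:NA"),
    as_med_row(product_name = "C EXT", ingredients = "c:5 mg"))
  expect_equal(meds$completeness,
               c("MISSING_PRODUCT", "MISSING_STRENGTH", "COMPLETE"))
  # product-name precedence: both missing -> MISSING_PRODUCT
  both <- as_med_row(product_name = NA, ingredients = "d:NA")
  expect_equal(both$completeness, "MISSING_PRODUCT")
})

test_that("main source is the largest field contributor, ties to priority", {
  rich_list <- rbind(
    src_row(source = "medication_list", product_name = "A", ingredients = "a:1 mg",
            dosage_form = "tablet", times = "1-0-0"),
    src_row(source = "interview", ingredients = "b:2 mg"))
  expect_equal(classify_main_source(source_records(rich_list)), "medication_list")
  # exact tie: interview wins under the default priority
  tie <- rbind(
    src_row(source = "interview", product_name = "A", ingredients = "a:1 mg"),
    src_row(source = "medication_list", product_name = "B", ingredients = "b:1 mg"))
  expect_equal(classify_main_source(source_records(tie)), "interview")
  only <- src_row(source = "interview", product_name = "A")
  expect_equal(classify_main_source(source_records(only)), "interview")
})

test_that("source records demand at least one identity field", {
  expect_error(source_records(src_row(source = "interview")),
               "at least one of product_name / ingredients")
  expect_error(source_records(data.frame(patient_id = "P", source = "fax",
                                         product_name = "A")),
               "source must be one of")
})
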