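test_that("formulary validates structure and rejects duplicates", {
  expect_equal(nrow(formulary(empty_products())), 0)
  dup <- data.frame(product_name = c("A 5mg", "a 5MG"), dosage_form = "tablet",
                    atc = NA, components = "a:5 mg", stringsAsFactors = FALSE)
  expect_error(formulary(dup), "duplicate product_name")
  bad <- data.frame(product_name = "X", dosage_form = "tablet", atc = "1BAD",
                    components = "x:5 mg", stringsAsFactors = FALSE)
  expect_error(formulary(bad), "letter expected")
})

test_that("the packaged default exclusion list holds exactly the seven ingredients", {
  x <- default_exclusion_list()
  expect_setequal(x$ingredient,
                  c("carbamazepine", "phenobarbital", "phenytoin", "primidone",
                    "valproic acid", "ciclosporin", "tacrolimus"))
  expect_equal(nrow(x), 7)
})

test_that("generic candidates: salt-specific matching as in the metoprolol case", {
  prods <- data.frame(
    product_name = "Metoprololsucc 95mg HSP", dosage_form = "retard-tablet",
    atc = "C07AB02", components = "metoprolol|succinate:95 mg",
    stringsAsFactors = FALSE)
  kb <- kb_of(prods)
  succ <- as_med_row(product_name = "Beloc-Zok EXT",
                     ingredients = "metoprolol|succinate:95 mg",
                     dosage_form = "retard-tablet")
  tart <- as_med_row(product_name = "Metoprololtart EXT",
                     ingredients = "metoprolol|tartrate:50 mg",
                     dosage_form = "retard-tablet")
  expect_equal(find_generic_candidates(succ, kb)$product_name,
               "Metoprololsucc 95mg HSP")
  expect_equal(nrow(find_generic_candidates(tart, kb)), 0)
  expect_equal(nrow(find_generic_candidates(succ, kb_of(empty_products()))), 0)
})

test_that("candidate search equals the brute-force filter on random formularies", {
  set.seed(421)
  for (rep in 1:40) {
    cs <- random_case(n_products = sample(5:100, 1))
    med <- as_med_row(product_name = cs$med_name, ingredients = cs$med_spec,
                      dosage_form = cs$med_form)
    got <- find_generic_candidates(med, kb_of(cs$products))$product_name
    want <- oracle_generic(cs$med_name, cs$med_spec, cs$med_form, cs$products)
    expect_equal(got, want)
  }
})

test_that("equivalence candidates require an explicit table entry at the exact dose", {
  prods <- data.frame(
    product_name = "Pantoprazole 40mg HSP", dosage_form = "tablet",
    atc = "A02BC02", components = "pantoprazole:40 mg", stringsAsFactors = FALSE)
  eq <- data.frame(table_id = "ppi", source_ingredient = "omeprazole",
                   source_strength = "20 mg", target_ingredient = "pantoprazole",
                   target_strength = "40 mg", match_level = 4L,
                   stringsAsFactors = FALSE)
  kb <- kb_of(prods, equivalence = eq)
  ome20 <- as_med_row(product_name = "Omep EXT", ingredients = "omeprazole:20 mg",
                      atc = "A02BC01")
  ome40 <- as_med_row(product_name = "Omep EXT", ingredients = "omeprazole:40 mg",
                      atc = "A02BC01")
  soli <- as_med_row(product_name = "Vesikur EXT", ingredients = "solifenacin:5 mg",
                     atc = "G04BD08")
  expect_equal(find_equivalence_candidates(ome20, kb)$product_name,
               "Pantoprazole 40mg HSP")
  expect_equal(nrow(find_equivalence_candidates(ome40, kb)), 0)  # dose not listed
  expect_equal(nrow(find_equivalence_candidates(soli, kb)), 0)   # no table
})

test_that("equivalence candidates verify ATC agreement at the entry level", {
  prods <- data.frame(
    product_name = "Target HSP", dosage_form = "tablet",
    atc = "C10AA07", components = "tgt:10 mg", stringsAsFactors = FALSE)
  eq <- data.frame(table_id = "t", source_ingredient = "src",
                   source_strength = "10 mg", target_ingredient = "tgt",
                   target_strength = "10 mg", match_level = 4L,
                   stringsAsFactors = FALSE)
  kb <- kb_of(prods, equivalence = eq)
  same_class <- as_med_row(product_name = "S EXT", ingredients = "src:10 mg",
                           atc = "C10AA01")
  other_class <- as_med_row(product_name = "S EXT", ingredients = "src:10 mg",
                            atc = "A02BC01")
  no_code <- as_med_row(product_name = "S EXT", ingredients = "src:10 mg")
  expect_equal(nrow(find_equivalence_candidates(same_class, kb)), 1)
  expect_equal(nrow(find_equivalence_candidates(other_class, kb)), 0)
  expect_equal(nrow(find_equivalence_candidates(no_code, kb)), 1)
})

test_that("a knowledge base survives the write/load round-trip", {
  kb <- paper_kb()
  dir <- withr::local_tempdir()
  kb_write(kb, dir)
  kb2 <- kb_load(dir)
  expect_equal(kb2$formulary, kb$formulary)
  expect_equal(kb2$exclusion, kb$exclusion)
  expect_equal(kb2$equivalence, kb$equivalence)
  expect_equal(kb2$interactions, kb$interactions)
  expect_equal(kb2$pim, kb$pim)
  expect_equal(kb2$synonyms, kb$synonyms)
  # second round trip is byte-stable
  dir2 <- withr::local_tempdir()
  kb_write(kb2, dir2)
  for (f in list.files(dir))
    expect_identical(readLines(file.path(dir2, f)), readLines(file.path(dir, f)))
})

test_that("the packaged extdata knowledge base equals the in-code one", {
  kb <- kb_load(system.file("extdata", "kb", package = "switchrx"))
  expect_equal(kb$formulary, paper_kb()$formulary)
  expect_equal(kb$equivalence, paper_kb()$equivalence)
  expect_equal(nrow(kb$exclusion), 7)
})

test_that("schema validation reports file and row", {
  dir <- withr::local_tempdir()
  kb_write(paper_kb(), dir)
  fm <- read.csv(file.path(dir, "formulary.csv"))
  fm$product_name[3] <- NA
  write.csv(fm, file.path(dir, "formulary.csv"), row.names = FALSE, na = "")
  expect_error(kb_load(dir), "formulary.csv.*row 3")
  fm$product_name[3] <- fm$product_name[4]  # duplicate name
  write.csv(fm, file.path(dir, "formulary.csv"), row.names = FALSE, na = "")
  expect_error(kb_load(dir), "duplicate product_name")
})
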