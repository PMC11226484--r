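# Independent brute-force oracles and random-case builders for the property
# tests. These deliberately re-derive results from first principles (plain
# loops over raw tables) and never call the engine's own search helpers.

# canonical (ingredient, salt, qty, qunit) multiset as a sorted string key
oracle_content_key <- function(spec) {
  comps <- parse_components(spec)
  if (any(is.na(comps$qty))) return(NA_character_)
  paste(sort(sprintf("%s/%s/%.10g/%s", comps$ingredient,
                     ifelse(is.na(comps$salt), "", comps$salt),
                     comps$qty, comps$qunit)), collapse = " ")
}

# exhaustive generic-candidate filter over a raw product table
oracle_generic <- function(med_name, med_spec, med_form, products) {
  key <- oracle_content_key(med_spec)
  hits <- character()
  for (i in seq_len(nrow(products))) {
    if (is.na(key)) break
    if (!identical(oracle_content_key(products$components[i]), key)) next
    if (tolower(products$dosage_form[i]) != tolower(med_form)) next
    if (!is.na(med_name) &&
        tolower(products$product_name[i]) == tolower(med_name)) next
    hits <- c(hits, products$product_name[i])
  }
  sort(hits)
}

# independent evaluation of the six cascade predicates; returns the first
# true one in order (gate-eligible medications only)
oracle_cascade <- function(med_row, products, exclusion, equivalence,
                           override_meds = character()) {
  spec <- med_row$ingredients
  key <- oracle_content_key(spec)
  comps <- parse_components(spec)
  form <- tolower(med_row$dosage_form)
  # S0
  for (i in seq_len(nrow(products)))
    if (!is.na(med_row$product_name) &&
        tolower(products$product_name[i]) == tolower(med_row$product_name) &&
        identical(oracle_content_key(products$components[i]), key) &&
        tolower(products$dosage_form[i]) == form) return("S0")
  # S1
  for (i in seq_len(nrow(comps)))
    if (comps$ingredient[i] %in% exclusion) return("S1")
  # S2: generic, or (combinations) all-or-nothing mono decomposition
  if (length(oracle_generic(med_row$product_name, spec, form, products)))
    return("S2")
  if (nrow(comps) >= 2L) {
    all_found <- TRUE
    for (i in seq_len(nrow(comps))) {
      ck <- oracle_content_key(sprintf("%s:%s %s", comps$ingredient[i],
                                       comps$amount[i], comps$unit[i]))
      found <- FALSE
      for (j in seq_len(nrow(products)))
        if (identical(oracle_content_key(products$components[j]), ck) &&
            tolower(products$dosage_form[j]) == form) found <- TRUE
      if (!found) all_found <- FALSE
    }
    if (all_found) return("S2")
  }
  # S3
  if (!is.null(equivalence))
    for (i in seq_len(nrow(equivalence))) {
      src <- oracle_content_key(paste(
        paste0(strsplit(equivalence$source_ingredient[i], ";")[[1]], ":",
               strsplit(equivalence$source_strength[i], ";")[[1]]),
        collapse = ";"))
      if (!identical(src, key)) next
      tgt <- oracle_content_key(paste(
        paste0(strsplit(equivalence$target_ingredient[i], ";")[[1]], ":",
               strsplit(equivalence$target_strength[i], ";")[[1]]),
        collapse = ";"))
      for (j in seq_len(nrow(products)))
        if (identical(oracle_content_key(products$components[j]), tgt) &&
            tolower(products$dosage_form[j]) == form) return("S3")
    }
  # S4
  if (!is.na(med_row$product_name) &&
      tolower(med_row$product_name) %in% tolower(override_meds)) return("S4")
  "S5"
}

# random single-patient medication + knowledge-base instance
random_case <- function(n_products = 30L, ing_pool = sprintf("ing%02d", 1:12),
                        strengths = c(5, 10, 20, 50)) {
  products <- data.frame(
    product_name = sprintf("RP%03d", seq_len(n_products)),
    dosage_form = sample(c("tablet", "capsule"), n_products, TRUE),
    atc = NA_character_,
    components = vapply(seq_len(n_products), function(i) {
      k <- sample(1:2, 1L, prob = c(0.8, 0.2))
      ings <- sample(ing_pool, k)
      paste(sprintf("%s:%g mg", ings, sample(strengths, k, TRUE)), collapse = ";")
    }, character(1L)),
    stringsAsFactors = FALSE)
  products <- products[!duplicated(tolower(products$product_name)), ]
  k <- sample(1:2, 1L, prob = c(0.8, 0.2))
  ings <- sample(ing_pool, k)
  med_spec <- paste(sprintf("%s:%g mg", ings, sample(strengths, k, TRUE)),
                    collapse = ";")
  med_name <- if (stats::runif(1) < 0.25)
    products$product_name[sample(nrow(products), 1L)] else
      sprintf("XP%03d", sample(999, 1L))
  list(products = products, med_name = med_name, med_spec = med_spec,
       med_form = sample(c("tablet", "capsule"), 1L))
}

# turn a bare medication description into a reconciled one-row record
as_med_row <- function(patient_id = "T1", product_name, ingredients,
                       dosage_form = "tablet", atc = NA_character_,
                       prescribed = TRUE, selfmed = FALSE) {
  src <- data.frame(patient_id = patient_id, source = "interview",
                    product_name = product_name, ingredients = ingredients,
                    dosage_form = dosage_form, atc = atc,
                    administration_times = "1-0-0",
                    prescribed_during_stay = prescribed,
                    self_medication = selfmed, stringsAsFactors = FALSE)
  merge_sources(source_records(src))
}

# minimal knowledge base from a raw product table
kb_of <- function(products, exclusion = NULL, equivalence = NULL,
                  interactions = NULL, pim = NULL) {
  knowledge_base(formulary = formulary(products),
                 exclusion = if (is.null(exclusion))
                   data.frame(ingredient = character(), salt = character())
                 else exclusion,
                 equivalence = equivalence, interactions = interactions,
                 pim = pim)
}

empty_products <- function() data.frame(
  product_name = character(), dosage_form = character(),
  atc = character(), components = character(), stringsAsFactors = FALSE)
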