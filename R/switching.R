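# The switching engine: information gates followed by the strict six-step
# cascade S0..S5. Every reconciled medication receives exactly one terminal
# status:
#   gates   NOT_PRESCRIBED -> SELF_MEDICATION -> MISSING_PRODUCT ->
#           MISSING_STRENGTH (first hit wins), else ELIGIBLE;
#   cascade S0 product listed in the formulary (no switch required)
#           S1 ingredient on the substitution-exclusion list (special request)
#           S2 generic "aut idem" switch (same ingredients + doses, stock)
#           S3 therapeutically equivalent "aut simile" switch via a
#              dose-equivalence table (stock)
#           S4 patient-individual switch from a pharmacist override (stock)
#           S5 no standardized or individual switch: wholesaler order.
# S0 is evaluated before S1: when the patient's exact product is stocked no
# switch occurs, so the exclusion list (which governs switching) is moot.

.gate_order <- c("NOT_PRESCRIBED", "SELF_MEDICATION", "MISSING_PRODUCT",
                 "MISSING_STRENGTH")
.step_order <- c("S0", "S1", "S2", "S3", "S4", "S5")
.status_levels <- c(.step_order, .gate_order)

.channel_of <- c(S0 = "stock", S2 = "stock", S3 = "stock", S4 = "stock",
                 S1 = "special_request", S5 = "wholesaler",
                 NOT_PRESCRIBED = "none", SELF_MEDICATION = "none",
                 MISSING_PRODUCT = "none", MISSING_STRENGTH = "none")

#' Information gates preceding the switching cascade
#'
#' Evaluated strictly in the order NOT_PRESCRIBED, SELF_MEDICATION,
#' MISSING_PRODUCT, MISSING_STRENGTH; the first hit wins. Medications
#' passing all gates are `ELIGIBLE` for the cascade.
#'
#' @param meds A reconciled medication table.
#' @return Character vector of gate statuses / `"ELIGIBLE"`.
#' @export
gate <- function(meds) {
  vapply(seq_len(nrow(meds)), function(i) {
    if (!meds$prescribed_during_stay[i]) return("NOT_PRESCRIBED")
    if (meds$self_medication[i]) return("SELF_MEDICATION")
    switch(meds$completeness[i],
           MISSING_PRODUCT = "MISSING_PRODUCT",
           MISSING_STRENGTH = "MISSING_STRENGTH",
           "ELIGIBLE")
  }, character(1L))
}

#' Resolve a combination product
#'
#' Preference order: (1) a combination-to-combination generic candidate;
#' (2) full decomposition, where every component has a mono-product in the
#' formulary at the exact strength and dosage-form class (all-or-nothing:
#' a partial decomposition falls through to the later steps). Either way the
#' original combination counts as a single switch.
#'
#' @param med A one-row eligible combination medication (>= 2 components).
#' @param kb A [knowledge_base()].
#' @return List with `mode` (`"combination"`, `"decomposition"` or
#'   `"none"`) and `targets` (character vector of formulary product names).
#' @export
decompose_combination <- function(med, kb) {
  stopifnot(med$n_components >= 2L)
  combo <- find_generic_candidates(med, kb)
  if (nrow(combo))
    return(list(mode = "combination", targets = combo$product_name[1L],
                candidates = combo$product_name))
  fm <- kb$formulary
  comps <- med$comps[[1L]]
  cls <- form_class(med$dosage_form, kb$form_classes)
  targets <- character(nrow(comps))
  for (i in seq_len(nrow(comps))) {
    sig <- component_signature(comps[i, , drop = FALSE])
    hit <- fm[fm$n_components == 1L & fm$signature == sig &
                form_class(fm$dosage_form, kb$form_classes) == cls, ,
              drop = FALSE]
    if (!nrow(hit)) return(list(mode = "none", targets = character()))
    targets[i] <- sort(hit$product_name)[1L]
  }
  list(mode = "decomposition", targets = targets, candidates = targets)
}

# S0 predicate + matched product
.match_s0 <- function(med, kb) {
  fm <- kb$formulary
  if (is.na(med$product_name) || is.na(med$signature)) return(character())
  hit <- fm[tolower(fm$product_name) == tolower(med$product_name) &
              fm$signature == med$signature &
              form_class(fm$dosage_form, kb$form_classes) ==
                form_class(med$dosage_form, kb$form_classes), , drop = FALSE]
  hit$product_name
}

# override lookup: by product name, or by ingredient multiset when the
# override names ingredients instead of a product
.match_override <- function(med, overrides, kb) {
  if (is.null(overrides) || nrow(overrides) == 0L) return(NULL)
  ov <- overrides[overrides$patient_id == med$patient_id, , drop = FALSE]
  if (!nrow(ov)) return(NULL)
  hit <- rep(FALSE, nrow(ov))
  for (i in seq_len(nrow(ov))) {
    m <- ov$medication[i]
    if (!is.na(med$product_name) && tolower(m) == tolower(med$product_name))
      hit[i] <- TRUE
    else {
      sig <- tryCatch(ingredient_signature(parse_components(m, kb$synonyms)),
                      error = function(e) NA_character_)
      if (!is.na(sig) && !is.na(med$ingredient_sig) && sig == med$ingredient_sig)
        hit[i] <- TRUE
    }
  }
  if (!any(hit)) return(NULL)
  ov <- ov[hit, , drop = FALSE][1L, ]
  if (!tolower(ov$target_product) %in% tolower(kb$formulary$product_name))
    stop(sprintf("override for %s / %s: target product '%s' is not in the formulary",
                 ov$patient_id, ov$medication, ov$target_product), call. = FALSE)
  ov
}

#' Classify one eligible medication through the S0-S5 cascade
#'
#' Applies the six switching steps in strict order and returns the first
#' match. See the module header for the step semantics.
#'
#' @param med A one-row eligible reconciled medication.
#' @param kb A [knowledge_base()].
#' @param overrides Optional pharmacist override table (`patient_id`,
#'   `medication`, `target_product`, `note`). Overrides are the only route
#'   to S4; the engine never self-promotes an equivalence-adjacent hint.
#' @return List with `status`, `targets`, `channel`, `rationale`.
#' @export
classify_switch <- function(med, kb, overrides = NULL) {
  own_kind <- if (med$n_components >= 2L) "combination" else "mono"
  # resolution of a formulary target: combination or mono product
  target_kind <- function(products) {
    hit <- match(tolower(products), tolower(kb$formulary$product_name))
    if (any(kb$formulary$n_components[hit] >= 2L)) "combination" else "mono"
  }
  s0 <- .match_s0(med, kb)
  if (length(s0))
    return(list(status = "S0", targets = s0[1L], channel = "stock",
                resolution = own_kind,
                rationale = "product listed in the hospital formulary; no switch required"))
  if (on_exclusion_list(med$comps[[1L]], kb$exclusion))
    return(list(status = "S1", targets = character(), channel = "special_request",
                resolution = own_kind,
                rationale = "ingredient on the substitution-exclusion list; order on special request signed by a senior physician"))
  if (med$n_components >= 2L) {
    dec <- decompose_combination(med, kb)
    if (dec$mode == "combination")
      return(list(status = "S2", targets = dec$targets, channel = "stock",
                  resolution = "combination",
                  rationale = paste0("generic combination product in formulary; candidates: ",
                                     paste(dec$candidates, collapse = ", "))))
    if (dec$mode == "decomposition")
      return(list(status = "S2", targets = dec$targets, channel = "stock",
                  resolution = "mono",
                  rationale = paste0("full decomposition into mono-products (counted as one switch): ",
                                     paste(dec$targets, collapse = " + "))))
  } else {
    gen <- find_generic_candidates(med, kb)
    if (nrow(gen))
      return(list(status = "S2", targets = gen$product_name[1L], channel = "stock",
                  resolution = "mono",
                  rationale = paste0("generic product(s) in formulary: ",
                                     paste(gen$product_name, collapse = ", "))))
  }
  eqc <- find_equivalence_candidates(med, kb)
  if (nrow(eqc))
    return(list(status = "S3", targets = eqc$product_name[1L], channel = "stock",
                resolution = target_kind(eqc$product_name[1L]),
                rationale = sprintf("equivalence table '%s' (ATC level %d): %s",
                                    eqc$table_id[1L], eqc$match_level[1L],
                                    paste(unique(eqc$product_name), collapse = ", "))))
  ov <- .match_override(med, overrides, kb)
  if (!is.null(ov))
    return(list(status = "S4", targets = ov$target_product, channel = "stock",
                resolution = target_kind(ov$target_product),
                rationale = paste0("patient-individual switch by pharmacist: ",
                                   if (is.na(ov$note)) "" else ov$note)))
  list(status = "S5", targets = character(), channel = "wholesaler",
       resolution = own_kind,
       rationale = "no standardized or patient-individual switch possible; wholesaler order")
}

#' Run gates and cascade over a whole cohort
#'
#' @param cohort A `cohort` object ([reconcile()]).
#' @param kb A [knowledge_base()].
#' @param overrides Optional override table (see [classify_switch()]).
#' @return A decisions data.frame: one row per medication with `status`,
#'   `targets` (list-column), `channel` and `rationale`. Statuses are
#'   exhaustive and exclusive; counts sum to the cohort medication count.
#' @export
switch_cohort <- function(cohort, kb, overrides = NULL) {
  meds <- cohort$medications
  n <- nrow(meds)
  status <- gate(meds)
  targets <- vector("list", n)
  rationale <- character(n)
  resolution <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (status[i] != "ELIGIBLE") {
      targets[[i]] <- character()
      rationale[i] <- switch(status[i],
        NOT_PRESCRIBED = "not prescribed during the hospital stay; no switch required",
        SELF_MEDICATION = "self-medication is not transferred to the formulary",
        MISSING_PRODUCT = "product name unknown; information completion required",
        MISSING_STRENGTH = "strength unknown; information completion required")
      next
    }
    d <- classify_switch(meds[i, , drop = FALSE], kb, overrides)
    status[i] <- d$status
    targets[[i]] <- d$targets
    rationale[i] <- d$rationale
    resolution[i] <- d$resolution
  }
  out <- data.frame(patient_id = meds$patient_id, med_id = meds$med_id,
                    product_name = meds$product_name,
                    ingredients = meds$ingredients,
                    n_components = meds$n_components,
                    status = status, resolution = resolution,
                    stringsAsFactors = FALSE)
  out$targets <- targets
  out$targets_chr <- vapply(targets, paste, character(1L), collapse = ";")
  out$channel <- unname(.channel_of[status])
  out$rationale <- rationale
  out
}

#' Build the pharmacy order list from switching decisions
#'
#' Orders are grouped by channel (stock, special request, wholesaler),
#' sorted by product name within each group, and aggregated per product.
#' Gate-status medications are listed separately as requiring information
#' completion.
#'
#' @param decisions Output of [switch_cohort()].
#' @return List with `orders` (channel, product_name, quantity) and
#'   `needs_information` (patient_id, med_id, reason).
#' @export
build_order_list <- function(decisions) {
  rows <- list()
  for (i in seq_len(nrow(decisions))) {
    st <- decisions$status[i]
    ch <- decisions$channel[i]
    if (ch == "none") next
    prods <- if (st %in% c("S0", "S2", "S3", "S4")) decisions$targets[[i]]
             else if (!is.na(decisions$product_name[i])) decisions$product_name[i]
             else decisions$ingredients[i]
    for (p in prods)
      rows[[length(rows) + 1L]] <- data.frame(channel = ch, product_name = p,
                                              stringsAsFactors = FALSE)
  }
  orders <- if (length(rows)) {
    x <- do.call(rbind, rows)
    agg <- stats::aggregate(list(quantity = rep(1L, nrow(x))),
                            by = list(channel = x$channel,
                                      product_name = x$product_name), FUN = sum)
    agg$channel <- factor(agg$channel,
                          levels = c("stock", "special_request", "wholesaler"))
    agg <- agg[order(agg$channel, agg$product_name), ]
    agg$channel <- as.character(agg$channel)
    rownames(agg) <- NULL
    agg
  } else data.frame(channel = character(), product_name = character(),
                    quantity = integer(), stringsAsFactors = FALSE)
  gates <- decisions$status %in% .gate_order
  needs <- data.frame(patient_id = decisions$patient_id[gates],
                      med_id = decisions$med_id[gates],
                      medication = ifelse(is.na(decisions$product_name[gates]),
                                          decisions$ingredients[gates],
                                          decisions$product_name[gates]),
                      reason = decisions$status[gates],
                      stringsAsFactors = FALSE)
  list(orders = orders, needs_information = needs)
}
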