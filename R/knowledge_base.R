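# Knowledge base: hospital formulary, substitution-exclusion list,
# dose-equivalence tables, drug-drug interaction table, PIM catalogs.
# All reference data the switching cascade and the pre-switch review consult.

#' Build a hospital formulary
#'
#' The formulary is the closed list of products the hospital pharmacy stocks.
#' Each product has a unique name, a dosage-form token, an optional ATC code
#' and one or more components (ingredient + strength); a product with two or
#' more components is a combination product.
#'
#' @param products A data.frame with columns `product_name`, `dosage_form`,
#'   `atc` (may be NA) and `components` (specification strings, see
#'   [parse_components()]).
#' @param synonyms Synonym map used to normalize ingredient names.
#' @return An object of class `formulary`: the input table augmented with a
#'   `comps` list-column, a canonical `signature`, and `n_components`.
#' @export
formulary <- function(products, synonyms = default_synonyms()) {
  if (nrow(products) == 0L) {
    out <- data.frame(product_name = character(), dosage_form = character(),
                      atc = character(), components = character(),
                      stringsAsFactors = FALSE)
    out$comps <- list()
    out$signature <- character()
    out$n_components <- integer()
    class(out) <- c("formulary", "data.frame")
    return(out)
  }
  need <- c("product_name", "dosage_form", "components")
  miss <- setdiff(need, names(products))
  if (length(miss))
    stop("formulary table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"atc" %in% names(products)) products$atc <- NA_character_
  if (anyDuplicated(tolower(products$product_name))) {
    dup <- products$product_name[duplicated(tolower(products$product_name))]
    stop("duplicate product_name in formulary: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  out <- products[, c("product_name", "dosage_form", "atc", "components")]
  out$atc <- as.character(out$atc)
  for (code in out$atc[!is.na(out$atc)]) parse_atc(code)  # validate
  out$comps <- lapply(out$components, parse_components, synonyms = synonyms)
  bad <- which(vapply(out$comps, nrow, integer(1L)) == 0L)
  if (length(bad))
    stop("formulary products without components: ",
         paste(out$product_name[bad], collapse = ", "), call. = FALSE)
  if (any(vapply(out$comps, function(cc) any(is.na(cc$qty)), logical(1L))))
    stop("formulary products must have known strengths", call. = FALSE)
  out$signature <- vapply(out$comps, component_signature, character(1L))
  out$n_components <- vapply(out$comps, nrow, integer(1L))
  rownames(out) <- NULL
  class(out) <- c("formulary", "data.frame")
  out
}

#' Packaged default substitution-exclusion list
#'
#' Narrow-therapeutic-index ingredients that must never be switched between
#' products (anticonvulsants and calcineurin inhibitors).
#' @return A data.frame with columns `ingredient`, `salt` (all NA: the
#'   exclusion applies to every salt of the ingredient).
#' @export
default_exclusion_list <- function() {
  data.frame(
    ingredient = c("carbamazepine", "phenobarbital", "phenytoin", "primidone",
                   "valproic acid", "ciclosporin", "tacrolimus"),
    salt = NA_character_, stringsAsFactors = FALSE)
}

#' Assemble a knowledge base
#'
#' @param formulary A [formulary()] object (or a raw product table).
#' @param exclusion Data.frame `ingredient`, `salt` (NA salt = any salt).
#' @param equivalence Data.frame with columns `table_id`, `source_ingredient`,
#'   `source_strength`, `target_ingredient`, `target_strength`, `match_level`.
#'   Multi-component sources/targets are semicolon-joined in parallel, so a
#'   whole combination product can map to one equivalent (usually they are
#'   single ingredients).
#' @param interactions Data.frame `ingredient_a`, `ingredient_b`, `severity`.
#'   Pairs are unordered; lookup is symmetric and salt-agnostic.
#' @param pim Data.frame `ingredient`, `catalog` (`"priscus"` or `"forta"`),
#'   `category` (FORTA only, one of A/B/C/D). PIM-positive means PRISCUS
#'   member or FORTA C/D.
#' @param synonyms Alias -> canonical ingredient map.
#' @param form_classes Optional named character vector mapping dosage-form
#'   tokens to coarser equivalence classes; the default (empty map) is exact
#'   form-token equality.
#' @return An object of class `knowledge_base`.
#' @export
knowledge_base <- function(formulary,
                           exclusion = default_exclusion_list(),
                           equivalence = NULL,
                           interactions = NULL,
                           pim = NULL,
                           synonyms = default_synonyms(),
                           form_classes = character()) {
  if (!inherits(formulary, "formulary")) formulary <- formulary(formulary, synonyms)
  exclusion <- .validate_exclusion(exclusion, synonyms)
  equivalence <- .validate_equivalence(equivalence, formulary, synonyms)
  interactions <- .validate_interactions(interactions, synonyms)
  pim <- .validate_pim(pim, synonyms)
  structure(list(formulary = formulary, exclusion = exclusion,
                 equivalence = equivalence, interactions = interactions,
                 pim = pim, synonyms = synonyms, form_classes = form_classes),
            class = "knowledge_base")
}

.validate_exclusion <- function(x, synonyms) {
  if (is.null(x)) x <- default_exclusion_list()
  if (!"salt" %in% names(x)) x$salt <- NA_character_
  x$ingredient <- norm_ingredient(x$ingredient, synonyms)
  x$salt <- ifelse(is.na(x$salt) | !nzchar(trimws(as.character(x$salt))),
                   NA_character_, tolower(trimws(as.character(x$salt))))
  x[, c("ingredient", "salt")]
}

.validate_equivalence <- function(x, formulary, synonyms) {
  empty <- data.frame(table_id = character(), source_ingredient = character(),
                      source_strength = character(), target_ingredient = character(),
                      target_strength = character(), match_level = integer(),
                      stringsAsFactors = FALSE)
  empty$source_comps <- list(); empty$target_comps <- list()
  empty$source_sig <- character(); empty$target_sig <- character()
  if (is.null(x) || nrow(x) == 0L) return(empty)
  need <- c("table_id", "source_ingredient", "source_strength",
            "target_ingredient", "target_strength", "match_level")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("equivalence table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- x[, need]
  x$match_level <- as.integer(x$match_level)
  if (any(is.na(x$match_level)) || !all(x$match_level %in% c(4L, 5L)))
    stop("equivalence match_level must be 4 or 5", call. = FALSE)
  pair_spec <- function(ing, strength) {
    ings <- strsplit(ing, ";", fixed = TRUE)[[1L]]
    strs <- strsplit(strength, ";", fixed = TRUE)[[1L]]
    if (length(ings) != length(strs))
      stop("equivalence entry: ingredient and strength lists differ in length",
           call. = FALSE)
    paste(paste0(trimws(ings), ":", trimws(strs)), collapse = ";")
  }
  x$source_comps <- lapply(seq_len(nrow(x)), function(i)
    parse_components(pair_spec(x$source_ingredient[i], x$source_strength[i]), synonyms))
  x$target_comps <- lapply(seq_len(nrow(x)), function(i)
    parse_components(pair_spec(x$target_ingredient[i], x$target_strength[i]), synonyms))
  x$source_sig <- vapply(x$source_comps, component_signature, character(1L))
  x$target_sig <- vapply(x$target_comps, component_signature, character(1L))
  if (any(is.na(x$source_sig)) || any(is.na(x$target_sig)))
    stop("equivalence entries must have known positive strengths", call. = FALSE)
  same <- vapply(seq_len(nrow(x)), function(i)
    ingredient_signature(x$source_comps[[i]]) == ingredient_signature(x$target_comps[[i]]),
    logical(1L))
  if (any(same))
    stop("equivalence entries must map between different ingredients", call. = FALSE)
  # assert ATC-level agreement at load time where codes exist (single-component
  # entries only: a combination ATC never shares level 4/5 with a mono target)
  atc_of <- function(comps) {
    if (nrow(comps) != 1L) return(NA_character_)
    hit <- which(vapply(formulary$comps, function(cc)
      nrow(cc) == 1L && cc$ingredient == comps$ingredient, logical(1L)))
    codes <- unique(stats::na.omit(formulary$atc[hit]))
    if (length(codes) == 1L) codes else NA_character_
  }
  for (i in seq_len(nrow(x))) {
    a <- atc_of(x$source_comps[[i]]); b <- atc_of(x$target_comps[[i]])
    if (!is.na(a) && !is.na(b) &&
        atc_level(parse_atc(a)) >= x$match_level[i] &&
        atc_level(parse_atc(b)) >= x$match_level[i] &&
        !atc_match(a, b, x$match_level[i]))
      stop(sprintf("equivalence entry %d (%s -> %s) violates ATC level %d agreement",
                   i, x$source_ingredient[i], x$target_ingredient[i], x$match_level[i]),
           call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

.validate_interactions <- function(x, synonyms) {
  if (is.null(x) || nrow(x) == 0L)
    return(data.frame(ingredient_a = character(), ingredient_b = character(),
                      severity = character(), stringsAsFactors = FALSE))
  need <- c("ingredient_a", "ingredient_b")
  if (!all(need %in% names(x)))
    stop("interaction table lacks ingredient_a/ingredient_b", call. = FALSE)
  if (!"severity" %in% names(x)) x$severity <- NA_character_
  x$ingredient_a <- norm_ingredient(x$ingredient_a, synonyms)
  x$ingredient_b <- norm_ingredient(x$ingredient_b, synonyms)
  if (any(x$ingredient_a == x$ingredient_b))
    stop("interaction table contains self-pairs", call. = FALSE)
  x[, c("ingredient_a", "ingredient_b", "severity")]
}

.validate_pim <- function(x, synonyms) {
  if (is.null(x) || nrow(x) == 0L)
    return(data.frame(ingredient = character(), catalog = character(),
                      category = character(), stringsAsFactors = FALSE))
  need <- c("ingredient", "catalog")
  if (!all(need %in% names(x)))
    stop("PIM table lacks ingredient/catalog columns", call. = FALSE)
  if (!"category" %in% names(x)) x$category <- NA_character_
  x$ingredient <- norm_ingredient(x$ingredient, synonyms)
  x$catalog <- tolower(x$catalog)
  if (!all(x$catalog %in% c("priscus", "forta")))
    stop("PIM catalog must be 'priscus' or 'forta'", call. = FALSE)
  forta <- x$catalog == "forta"
  x$category[forta] <- toupper(x$category[forta])
  if (any(forta & !x$category %in% c("A", "B", "C", "D")))
    stop("FORTA categories must be A, B, C or D", call. = FALSE)
  x$category[!forta] <- NA_character_
  x[, c("ingredient", "catalog", "category")]
}

# dosage-form equivalence class of a form token
form_class <- function(form, form_classes = character()) {
  form <- tolower(trimws(form))
  out <- form
  hit <- match(form, names(form_classes))
  out[!is.na(hit)] <- unname(form_classes[hit[!is.na(hit)]])
  out
}

# does the formulary list this exact product (name + content + form)?
formulary_lists <- function(med, kb) {
  fm <- kb$formulary
  if (is.na(med$product_name) || is.na(med$signature)) return(FALSE)
  any(tolower(fm$product_name) == tolower(med$product_name) &
        fm$signature == med$signature &
        form_class(fm$dosage_form, kb$form_classes) ==
          form_class(med$dosage_form, kb$form_classes))
}

# is any component of the med on the substitution-exclusion list?
on_exclusion_list <- function(comps, exclusion) {
  if (nrow(exclusion) == 0L || nrow(comps) == 0L) return(FALSE)
  for (i in seq_len(nrow(comps))) {
    hit <- exclusion$ingredient == comps$ingredient[i] &
      (is.na(exclusion$salt) |
         (!is.na(comps$salt[i]) & exclusion$salt == comps$salt[i]))
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Find generic ("aut idem") switching candidates
#'
#' Returns every formulary product with exactly the same component multiset
#' (ingredient key and normalized strength), the same dosage-form class and a
#' different product name than the medication, ordered by ascending product
#' name (the deterministic tie-break).
#'
#' @param med A one-row medication record (see [merge_sources()]) with known
#'   product name, strengths and dosage form.
#' @param kb A [knowledge_base()] (or a bare [formulary()], in which case
#'   default form classes apply).
#' @return A `formulary` subset (possibly empty).
#' @export
find_generic_candidates <- function(med, kb) {
  if (inherits(kb, "formulary")) kb <- list(formulary = kb, form_classes = character())
  fm <- kb$formulary
  if (is.na(med$signature) || nrow(fm) == 0L) return(fm[0L, ])
  keep <- fm$signature == med$signature &
    form_class(fm$dosage_form, kb$form_classes) ==
      form_class(med$dosage_form, kb$form_classes)
  if (!is.na(med$product_name))
    keep <- keep & tolower(fm$product_name) != tolower(med$product_name)
  out <- fm[keep, , drop = FALSE]
  out[order(out$product_name), , drop = FALSE]
}

#' Find therapeutically equivalent ("aut simile") switching candidates
#'
#' A candidate pairs a dose-equivalence entry whose source component multiset
#' exactly matches the medication with a formulary product matching the
#' entry's target multiset and the medication's dosage-form class. Switching
#' is only proposed when explicitly stated on an equivalence table; when both
#' the medication and the target product carry ATC codes (single-ingredient
#' entries), agreement at the entry's match level is verified.
#'
#' @inheritParams find_generic_candidates
#' @return A data.frame with columns `table_id`, `match_level`,
#'   `product_name`, `entry_row`, ordered by table_id then product name.
#' @export
find_equivalence_candidates <- function(med, kb) {
  eq <- kb$equivalence
  empty <- data.frame(table_id = character(), match_level = integer(),
                      product_name = character(), entry_row = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(eq) || nrow(eq) == 0L || is.na(med$signature)) return(empty)
  hits <- which(eq$source_sig == med$signature)
  if (!length(hits)) return(empty)
  fm <- kb$formulary
  out <- empty
  for (i in hits) {
    keep <- fm$signature == eq$target_sig[i] &
      form_class(fm$dosage_form, kb$form_classes) ==
        form_class(med$dosage_form, kb$form_classes)
    prods <- fm[keep, , drop = FALSE]
    if (!nrow(prods)) next
    if (nrow(eq$source_comps[[i]]) == 1L && nrow(eq$target_comps[[i]]) == 1L &&
        !is.null(med$atc) && !is.na(med$atc)) {
      ok <- vapply(seq_len(nrow(prods)), function(j) {
        if (is.na(prods$atc[j])) return(TRUE)
        a <- parse_atc(med$atc); b <- parse_atc(prods$atc[j])
        if (atc_level(a) < eq$match_level[i] || atc_level(b) < eq$match_level[i])
          return(TRUE)
        atc_match(a, b, eq$match_level[i])
      }, logical(1L))
      prods <- prods[ok, , drop = FALSE]
    }
    if (nrow(prods))
      out <- rbind(out, data.frame(table_id = eq$table_id[i],
                                   match_level = eq$match_level[i],
                                   product_name = prods$product_name,
                                   entry_row = i, stringsAsFactors = FALSE))
  }
  out[order(out$table_id, out$product_name), , drop = FALSE]
}
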