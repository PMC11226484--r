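# Medication reconciliation: merging per-patient medication information from
# the three admission sources (pharmacist interview, brought-in medication
# lists, medical documents) into one reconciled record per medication, with
# per-field provenance, conflict surfacing and completeness flags.

.sources_enum <- c("interview", "medication_list", "medical_documents")
.default_priority <- .sources_enum  # interview is the richest source

#' Validate a table of medication source records
#'
#' @param df Data.frame with columns `patient_id`, `source` (one of
#'   interview / medication_list / medical_documents), `product_name`,
#'   `ingredients` (component specification string, see
#'   [parse_components()]), `dosage_form`, `atc`, `administration_times`,
#'   `prescribed_during_stay`, `self_medication`. At least one of
#'   `product_name` / `ingredients` must be present on every row.
#' @param synonyms Ingredient synonym map.
#' @return The validated table (class `source_records`) with a `comps`
#'   list-column of parsed components.
#' @export
source_records <- function(df, synonyms = default_synonyms()) {
  opt <- c(product_name = NA_character_, ingredients = NA_character_,
           dosage_form = NA_character_, atc = NA_character_,
           administration_times = NA_character_)
  for (nm in names(opt)) if (!nm %in% names(df)) df[[nm]] <- opt[[nm]]
  if (!"prescribed_during_stay" %in% names(df)) df$prescribed_during_stay <- NA
  if (!"self_medication" %in% names(df)) df$self_medication <- NA
  if (!all(c("patient_id", "source") %in% names(df)))
    stop("source records need patient_id and source columns", call. = FALSE)
  if (!all(df$source %in% .sources_enum))
    stop("source must be one of: ", paste(.sources_enum, collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(df$product_name) &
                 (is.na(df$ingredients) | !nzchar(trimws(df$ingredients))))
  if (length(bad))
    stop("source record row ", bad[1L],
         ": at least one of product_name / ingredients required", call. = FALSE)
  df$prescribed_during_stay <- as.logical(df$prescribed_during_stay)
  df$self_medication <- as.logical(df$self_medication)
  df$comps <- lapply(df$ingredients, function(s)
    parse_components(if (is.na(s)) NA_character_ else s, synonyms))
  class(df) <- c("source_records", class(df))
  df
}

# identity key of one record: product name first, ingredient multiset fallback
.med_identity <- function(product_name, comps) {
  if (!is.na(product_name)) paste0("N:", tolower(trimws(product_name)))
  else paste0("I:", ingredient_signature(comps))
}

#' Merge one patient's source records into reconciled medications
#'
#' Records referring to the same medication (same product name, or same
#' ingredient multiset when the product name is absent on one side) collapse
#' to a single record; each field is filled from the highest-priority source
#' providing it and the contributing source is recorded per field.
#' Conflicting non-missing strengths across sources are surfaced as a
#' conflict flag, never silently overridden.
#'
#' @param records A [source_records()] table for a single patient.
#' @param priority Permutation of the three sources, highest first.
#' @return A data.frame of reconciled medications (one row per medication)
#'   with list-columns `comps` (components) and `provenance` (field ->
#'   source), plus `completeness` and `conflict` flags.
#' @export
merge_sources <- function(records, priority = .default_priority) {
  if (!inherits(records, "source_records")) records <- source_records(records)
  stopifnot(length(unique(records$patient_id)) <= 1L)
  if (!setequal(priority, .sources_enum))
    stop("priority must be a permutation of the three sources", call. = FALSE)
  if (nrow(records) == 0L) return(.empty_meds())
  records$prio <- match(records$source, priority)
  key <- vapply(seq_len(nrow(records)), function(i)
    .med_identity(records$product_name[i], records$comps[[i]]), character(1L))
  # ingredient-multiset fallback: an unnamed record joins a named group when
  # its ingredient multiset matches exactly one named group
  named <- unique(key[startsWith(key, "N:")])
  named_sig <- vapply(named, function(k) {
    i <- which(key == k)
    sigs <- unique(stats::na.omit(vapply(records$comps[i], ingredient_signature,
                                         character(1L))))
    if (length(sigs) == 1L) sigs else NA_character_
  }, character(1L))
  for (k in unique(key[startsWith(key, "I:")])) {
    sig <- sub("^I:", "", k)
    hit <- named[!is.na(named_sig) & named_sig == sig]
    if (length(hit) == 1L) key[key == k] <- hit
  }
  out <- lapply(unique(key), function(k) {
    grp <- records[key == k, , drop = FALSE]
    grp <- grp[order(grp$prio), , drop = FALSE]
    prov <- list()
    pick <- function(field) {
      vals <- grp[[field]]
      i <- which(!is.na(vals))[1L]
      if (is.na(i)) return(NA)
      prov[[field]] <<- grp$source[i]
      vals[i]
    }
    product_name <- pick("product_name")
    dosage_form <- pick("dosage_form")
    atc <- pick("atc")
    administration_times <- pick("administration_times")
    prescribed <- pick("prescribed_during_stay")
    selfmed <- pick("self_medication")
    # components: ingredient list from the best source providing one, then
    # missing strengths completed from lower-priority sources
    conflict <- FALSE; conflict_detail <- NA_character_
    have <- which(vapply(grp$comps, nrow, integer(1L)) > 0L)
    comps <- if (length(have)) grp$comps[[have[1L]]] else .empty_comps()
    if (length(have)) {
      prov[["ingredients"]] <- grp$source[have[1L]]
      strength_src <- rep(grp$source[have[1L]], nrow(comps))
      for (j in have[-1L]) {
        other <- grp$comps[[j]]
        for (r in seq_len(nrow(comps))) {
          m <- which(other$ingredient == comps$ingredient[r] &
                       (is.na(other$salt) & is.na(comps$salt[r]) |
                          (!is.na(other$salt) & !is.na(comps$salt[r]) &
                             other$salt == comps$salt[r])))
          if (!length(m)) next
          if (is.na(comps$qty[r]) && !is.na(other$qty[m[1L]])) {
            comps[r, c("amount", "unit", "qty", "qunit")] <-
              other[m[1L], c("amount", "unit", "qty", "qunit")]
            strength_src[r] <- grp$source[j]
          } else if (!is.na(comps$qty[r]) && !is.na(other$qty[m[1L]]) &&
                       (comps$qty[r] != other$qty[m[1L]] ||
                          comps$qunit[r] != other$qunit[m[1L]])) {
            conflict <- TRUE
            conflict_detail <- sprintf(
              "strength of %s: %s from %s vs %s from %s",
              comps$ingredient[r],
              paste(comps$qty[r], comps$qunit[r]), strength_src[r],
              paste(other$qty[m[1L]], other$qunit[m[1L]]), grp$source[j])
          }
        }
      }
      if (any(!is.na(comps$qty))) prov[["strengths"]] <- strength_src[1L]
    }
    med <- data.frame(patient_id = grp$patient_id[1L],
                      product_name = product_name,
                      ingredients = format_components(comps),
                      dosage_form = dosage_form, atc = atc,
                      administration_times = administration_times,
                      prescribed_during_stay = if (is.na(prescribed)) TRUE else prescribed,
                      self_medication = if (is.na(selfmed)) FALSE else selfmed,
                      conflict = conflict, conflict_detail = conflict_detail,
                      stringsAsFactors = FALSE)
    med$comps <- list(comps)
    med$provenance <- list(prov)
    med
  })
  out <- do.call(rbind, out)
  out$signature <- vapply(out$comps, component_signature, character(1L))
  out$ingredient_sig <- vapply(out$comps, ingredient_signature, character(1L))
  out$n_components <- vapply(out$comps, nrow, integer(1L))
  out$completeness <- completeness_status(out)
  rownames(out) <- NULL
  out
}

.empty_comps <- function() {
  data.frame(ingredient = character(), salt = character(), amount = numeric(),
             unit = character(), qty = numeric(), qunit = character(),
             stringsAsFactors = FALSE)
}

.empty_meds <- function() {
  out <- data.frame(patient_id = character(), product_name = character(),
                    ingredients = character(), dosage_form = character(),
                    atc = character(), administration_times = character(),
                    prescribed_during_stay = logical(),
                    self_medication = logical(), conflict = logical(),
                    conflict_detail = character(), stringsAsFactors = FALSE)
  out$comps <- list(); out$provenance <- list()
  out$signature <- character(); out$ingredient_sig <- character()
  out$n_components <- integer(); out$completeness <- character()
  out
}

#' Completeness status of reconciled medications
#'
#' `MISSING_PRODUCT` when the product name is absent (takes precedence),
#' `MISSING_STRENGTH` when the product name is present but any component
#' strength is unknown, `COMPLETE` otherwise.
#'
#' @param meds A reconciled medication table ([merge_sources()]).
#' @return Character vector, one status per medication.
#' @export
completeness_status <- function(meds) {
  vapply(seq_len(nrow(meds)), function(i) {
    if (is.na(meds$product_name[i])) return("MISSING_PRODUCT")
    comps <- meds$comps[[i]]
    if (nrow(comps) == 0L || any(is.na(comps$qty))) return("MISSING_STRENGTH")
    "COMPLETE"
  }, character(1L))
}

#' Main information source of one patient's reconciliation
#'
#' The source contributing the most filled fields across the patient's
#' source records; ties are broken by the priority order.
#'
#' @param records A [source_records()] table for one patient.
#' @param priority Permutation of the three sources, highest first.
#' @return One of `"interview"`, `"medication_list"`, `"medical_documents"`.
#' @export
classify_main_source <- function(records, priority = .default_priority) {
  if (!inherits(records, "source_records")) records <- source_records(records)
  if (nrow(records) == 0L) stop("no source records", call. = FALSE)
  filled <- vapply(seq_len(nrow(records)), function(i) {
    n <- sum(!is.na(c(records$product_name[i], records$dosage_form[i],
                      records$atc[i], records$administration_times[i],
                      records$prescribed_during_stay[i],
                      records$self_medication[i])))
    comps <- records$comps[[i]]
    if (nrow(comps) > 0L) n <- n + 1L
    if (nrow(comps) > 0L && any(!is.na(comps$qty))) n <- n + 1L
    n
  }, integer(1L))
  totals <- vapply(priority, function(s) sum(filled[records$source == s]),
                   integer(1L))
  priority[which.max(totals)]  # which.max takes the first (= highest priority)
}

#' Reconcile a whole cohort
#'
#' Runs [merge_sources()] per patient and assembles a cohort object.
#'
#' @param sources A [source_records()] table (any number of patients).
#' @param patients Optional demographics table with `patient_id`, `age`,
#'   `department`. Patients without source records are kept (empty
#'   medication list).
#' @param priority Source priority, highest first.
#' @return An object of class `cohort`: a list with `patients` (demographics
#'   plus `main_source`) and `medications` (reconciled records, one row per
#'   medication, with `med_id`).
#' @export
reconcile <- function(sources, patients = NULL, priority = .default_priority) {
  if (!inherits(sources, "source_records")) sources <- source_records(sources)
  ids <- if (!is.null(patients)) patients$patient_id else unique(sources$patient_id)
  meds <- lapply(ids, function(pid)
    merge_sources(sources[sources$patient_id == pid, , drop = FALSE], priority))
  meds <- do.call(rbind, meds)
  if (is.null(meds)) meds <- .empty_meds()
  if (nrow(meds)) meds$med_id <- sprintf("M%04d", seq_len(nrow(meds)))
  else meds$med_id <- character()
  if (is.null(patients))
    patients <- data.frame(patient_id = ids, age = NA_integer_,
                           department = NA_character_, stringsAsFactors = FALSE)
  patients$main_source <- vapply(patients$patient_id, function(pid) {
    rec <- sources[sources$patient_id == pid, , drop = FALSE]
    if (nrow(rec) == 0L) NA_character_ else classify_main_source(rec, priority)
  }, character(1L))
  structure(list(patients = patients, medications = meds), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients, %d medications\n",
              nrow(x$patients), nrow(x$medications)))
  invisible(x)
}
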