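# Pre-switch medication review: pairwise drug-drug interaction screening and
# potentially-inappropriate-medication screening (PRISCUS membership or
# FORTA category C/D at age >= 65), with cohort-level aggregation.
#
# Interaction and PIM lookup is by ingredient name (salt-agnostic): the
# property belongs to the active moiety, not to a particular salt.

#' All concomitant ingredient pairs of a medication list
#'
#' Medications are first filtered to those prescribed during the stay;
#' combination products contribute each component. Returns every unordered
#' pair of distinct ingredient names, without duplicates.
#'
#' @param meds A reconciled medication table for one patient.
#' @return Data.frame with columns `ingredient_a`, `ingredient_b`
#'   (alphabetical within pair).
#' @export
concomitant_pairs <- function(meds) {
  meds <- meds[meds$prescribed_during_stay, , drop = FALSE]
  ings <- sort(unique(unlist(lapply(meds$comps, function(cc) cc$ingredient))))
  if (length(ings) < 2L)
    return(data.frame(ingredient_a = character(), ingredient_b = character(),
                      stringsAsFactors = FALSE))
  idx <- utils::combn(length(ings), 2L)
  data.frame(ingredient_a = ings[idx[1L, ]], ingredient_b = ings[idx[2L, ]],
             stringsAsFactors = FALSE)
}

# number of concomitant medications (records prescribed during the stay)
n_concomitant <- function(meds) sum(meds$prescribed_during_stay)

#' Screen one patient for drug-drug interactions
#'
#' A patient is assessable when at least two medications are prescribed
#' during the stay; otherwise the result carries `assessable = FALSE` and
#' the patient is excluded from cohort denominators. Findings are exactly
#' the concomitant ingredient pairs present in the interaction table
#' (symmetric in pair order).
#'
#' @param meds Reconciled medications of one patient.
#' @param kb A [knowledge_base()] (its `interactions` table is used).
#' @return List with `assessable` (logical) and `findings` (data.frame
#'   `ingredient_a`, `ingredient_b`, `severity`, `medications`).
#' @export
screen_ddi <- function(meds, kb) {
  tab <- if (inherits(kb, "knowledge_base")) kb$interactions else kb
  empty <- data.frame(ingredient_a = character(), ingredient_b = character(),
                      severity = character(), medications = character(),
                      stringsAsFactors = FALSE)
  if (n_concomitant(meds) < 2L)
    return(list(assessable = FALSE, findings = empty))
  pairs <- concomitant_pairs(meds)
  if (nrow(pairs) == 0L || nrow(tab) == 0L)
    return(list(assessable = TRUE, findings = empty))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tab_key <- key(tab$ingredient_a, tab$ingredient_b)
  hit <- match(key(pairs$ingredient_a, pairs$ingredient_b), tab_key)
  found <- pairs[!is.na(hit), , drop = FALSE]
  if (nrow(found) == 0L) return(list(assessable = TRUE, findings = empty))
  found$severity <- tab$severity[hit[!is.na(hit)]]
  conc <- meds[meds$prescribed_during_stay, , drop = FALSE]
  found$medications <- vapply(seq_len(nrow(found)), function(i) {
    has <- vapply(conc$comps, function(cc)
      any(cc$ingredient %in% c(found$ingredient_a[i], found$ingredient_b[i])),
      logical(1L))
    labs <- ifelse(is.na(conc$product_name[has]),
                   conc$ingredients[has], conc$product_name[has])
    paste(labs, collapse = " + ")
  }, character(1L))
  rownames(found) <- NULL
  list(assessable = TRUE, findings = found)
}

#' Screen one patient for potentially inappropriate medication
#'
#' Empty below the age threshold; otherwise one finding per distinct
#' ingredient that is a PRISCUS member or FORTA category C/D.
#'
#' @param age Patient age in years.
#' @param meds Reconciled medications of the patient.
#' @param kb A [knowledge_base()] (its `pim` table is used).
#' @param age_threshold Age gate in years (default 65).
#' @return Data.frame with columns `ingredient`, `catalog`, `category`.
#' @export
screen_pim <- function(age, meds, kb, age_threshold = 65) {
  tab <- if (inherits(kb, "knowledge_base")) kb$pim else kb
  empty <- data.frame(ingredient = character(), catalog = character(),
                      category = character(), stringsAsFactors = FALSE)
  if (is.na(age) || age < age_threshold || nrow(tab) == 0L) return(empty)
  ings <- unique(unlist(lapply(meds$comps, function(cc) cc$ingredient)))
  pos <- tab[tab$ingredient %in% ings &
               (tab$catalog == "priscus" | tab$category %in% c("C", "D")), ,
             drop = FALSE]
  pos <- pos[!duplicated(pos$ingredient), , drop = FALSE]
  pos <- pos[order(pos$ingredient), , drop = FALSE]
  rownames(pos) <- NULL
  pos
}

#' Cohort-level medication review
#'
#' Runs DDI and PIM screening per patient and aggregates: assessable
#' patients (at least two concomitant medications), patients with at least
#' one interaction, patients aged 65+ and those among them with at least one
#' PIM, and the most frequent interacting ingredients (ties alphabetical).
#'
#' @param cohort A `cohort` object (see [reconcile()]).
#' @param kb A [knowledge_base()].
#' @param age_threshold PIM age gate in years.
#' @return List of class `review_report` with per-patient findings and the
#'   aggregate counts.
#' @export
review_report <- function(cohort, kb, age_threshold = 65) {
  pts <- cohort$patients
  meds_of <- split(seq_len(nrow(cohort$medications)),
                   factor(cohort$medications$patient_id, levels = pts$patient_id))
  ddi_rows <- list(); pim_rows <- list()
  assessable <- logical(nrow(pts)); has_ddi <- logical(nrow(pts))
  has_pim <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    meds <- cohort$medications[meds_of[[i]], , drop = FALSE]
    d <- screen_ddi(meds, kb)
    assessable[i] <- d$assessable
    has_ddi[i] <- nrow(d$findings) > 0L
    if (has_ddi[i])
      ddi_rows[[length(ddi_rows) + 1L]] <-
        cbind(patient_id = pts$patient_id[i], d$findings)
    p <- screen_pim(pts$age[i], meds, kb, age_threshold)
    has_pim[i] <- nrow(p) > 0L
    if (has_pim[i])
      pim_rows[[length(pim_rows) + 1L]] <-
        cbind(patient_id = pts$patient_id[i], p)
  }
  ddi <- if (length(ddi_rows)) do.call(rbind, ddi_rows) else
    data.frame(patient_id = character(), ingredient_a = character(),
               ingredient_b = character(), severity = character(),
               medications = character(), stringsAsFactors = FALSE)
  pim <- if (length(pim_rows)) do.call(rbind, pim_rows) else
    data.frame(patient_id = character(), ingredient = character(),
               catalog = character(), category = character(),
               stringsAsFactors = FALSE)
  inv <- c(ddi$ingredient_a, ddi$ingredient_b)
  top <- if (length(inv)) {
    tt <- table(inv)
    tt <- tt[order(-as.integer(tt), names(tt))]  # ties alphabetical
    data.frame(ingredient = names(tt), n_interactions = as.integer(tt),
               stringsAsFactors = FALSE)
  } else data.frame(ingredient = character(), n_interactions = integer(),
                    stringsAsFactors = FALSE)
  older <- !is.na(pts$age) & pts$age >= age_threshold
  structure(list(
    n_patients = nrow(pts),
    n_assessable = sum(assessable),
    n_with_ddi = sum(has_ddi),
    n_aged_65plus = sum(older),
    n_with_pim = sum(has_pim & older),
    ddi_findings = ddi,
    pim_findings = pim,
    top_interacting = top,
    age_threshold = age_threshold), class = "review_report")
}

#' @export
print.review_report <- function(x, ...) {
  cat(sprintf("<review_report> DDI: %d/%d assessable patients; PIM: %d/%d aged %d+\n",
              x$n_with_ddi, x$n_assessable, x$n_with_pim, x$n_aged_65plus,
              x$age_threshold))
  invisible(x)
}
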