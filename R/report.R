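# Summary statistics and end-to-end pipeline orchestration.

#' Round half up
#'
#' Commercial rounding (0.05 -> 0.1), matching the reporting convention of
#' the summary tables; R's `round()` rounds half to even.
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Quartiles by the linear-interpolation order-statistic convention
#'
#' Q25, median and Q75 computed with the common "type 7" rule (linear
#' interpolation between order statistics), the fixed convention of this
#' package's summaries.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector `c(q25, median, q75)`.
#' @export
quartiles <- function(values) {
  if (length(values) == 0L || all(is.na(values)))
    stop("quartiles() needs a non-empty vector", call. = FALSE)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7,
                       na.rm = TRUE, names = FALSE)
  c(q25 = q[1L], median = q[2L], q75 = q[3L])
}

#' Summarize a pipeline run
#'
#' Per-status counts and percentages over all medications (gate statuses
#' share the same denominator), per-patient medication-count and age
#' quartiles, the combination-product sub-analysis, the main-source
#' breakdown, and the review rates over their stated denominators
#' (drug-drug interactions over patients with at least two concomitant
#' medications, PIM over patients aged 65+). Percentages are rounded to one
#' decimal, half up.
#'
#' @param decisions Output of [switch_cohort()].
#' @param cohort The `cohort` the decisions were computed from.
#' @param review Optional [review_report()].
#' @return A list of class `summary_report`.
#' @export
summarize_pipeline <- function(decisions, cohort, review = NULL) {
  total <- nrow(decisions)
  counts <- vapply(.status_levels, function(s) sum(decisions$status == s),
                   integer(1L))
  status_table <- data.frame(status = .status_levels, n = unname(counts),
                             pct = round_half_up(100 * unname(counts) / max(total, 1L), 1),
                             stringsAsFactors = FALSE)
  per_patient <- as.integer(table(factor(decisions$patient_id,
                                         levels = cohort$patients$patient_id)))
  med_q <- quartiles(per_patient)
  age_q <- if (all(is.na(cohort$patients$age))) c(q25 = NA_real_, median = NA_real_, q75 = NA_real_)
           else quartiles(cohort$patients$age)
  # combination sub-analysis
  is_combo <- decisions$n_components >= 2L
  cd <- decisions[is_combo, , drop = FALSE]
  combo_counts <- vapply(.status_levels, function(s) sum(cd$status == s),
                         integer(1L))
  to_mono <- sum(cd$status %in% c("S2", "S3", "S4") & cd$resolution == "mono",
                 na.rm = TRUE)
  to_combo <- sum(cd$status %in% c("S0", "S5") |
                    (cd$status %in% c("S2", "S3", "S4") &
                       cd$resolution == "combination"), na.rm = TRUE)
  combo <- list(n = nrow(cd),
                by_status = data.frame(status = .status_levels,
                                       n = unname(combo_counts),
                                       stringsAsFactors = FALSE),
                switched_to_mono = to_mono,
                resolved_as_combination = to_combo,
                pct_mono = round_half_up(100 * to_mono / max(nrow(cd), 1L), 1),
                pct_combination = round_half_up(100 * to_combo / max(nrow(cd), 1L), 1))
  main_source <- table(factor(cohort$patients$main_source, levels = .sources_enum))
  out <- list(
    n_patients = nrow(cohort$patients),
    n_medications = total,
    n_active_ingredients = sum(decisions$n_components),
    status_table = status_table,
    medications_per_patient = as.list(med_q),
    age = as.list(age_q),
    n_aged_65plus = sum(!is.na(cohort$patients$age) & cohort$patients$age >= 65),
    combination_products = combo,
    main_source = as.list(as.integer(main_source)) |>
      stats::setNames(.sources_enum))
  if (!is.null(review)) {
    out$review <- list(
      n_assessable = review$n_assessable,
      n_with_ddi = review$n_with_ddi,
      pct_ddi = round_half_up(100 * review$n_with_ddi / max(review$n_assessable, 1L), 1),
      n_aged_65plus = review$n_aged_65plus,
      n_with_pim = review$n_with_pim,
      pct_pim = round_half_up(100 * review$n_with_pim / max(review$n_aged_65plus, 1L), 1))
  }
  class(out) <- "summary_report"
  out
}

#' @export
print.summary_report <- function(x, ...) {
  cat(sprintf("<summary_report> %d medications in %d patients (median %g per patient)\n",
              x$n_medications, x$n_patients, x$medications_per_patient$median))
  st <- x$status_table[x$status_table$n > 0L, ]
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-16s %4d  (%5.1f%%)\n", st$status[i], st$n[i], st$pct[i]))
  if (!is.null(x$review))
    cat(sprintf("  DDI %d/%d patients (%.0f%%); PIM %d/%d aged 65+ (%.0f%%)\n",
                x$review$n_with_ddi, x$review$n_assessable, x$review$pct_ddi,
                x$review$n_with_pim, x$review$n_aged_65plus, x$review$pct_pim))
  invisible(x)
}

# read a cohort directory (patients.csv, sources.csv, optional overrides.csv)
cohort_read <- function(dir) {
  sp <- file.path(dir, "sources.csv")
  if (!file.exists(sp)) stop("cohort file not found: ", sp, call. = FALSE)
  sources <- validate_table(.read_kb_csv(sp), "sources", "sources.csv")
  pp <- file.path(dir, "patients.csv")
  patients <- if (file.exists(pp))
    validate_table(.read_kb_csv(pp), "patients", "patients.csv") else NULL
  op <- file.path(dir, "overrides.csv")
  overrides <- if (file.exists(op))
    validate_table(.read_kb_csv(op), "overrides", "overrides.csv") else NULL
  list(sources = sources, patients = patients, overrides = overrides)
}

#' Run the full pipeline and write its artifacts
#'
#' Reconciliation, medication review, switching, order list and summary in
#' one call. Writes `decisions.csv`, `orders.csv`, `needs_information.csv`,
#' `review_findings.csv`, `summary.json` and `summary.md` into `out_dir`.
#' Identical inputs produce byte-identical outputs.
#'
#' @param kb Either a [knowledge_base()] or a directory for [kb_load()].
#' @param cohort Either a list with `sources` / `patients` / `overrides`
#'   data.frames (as from [build_paper_fixture()]), or a directory holding
#'   `sources.csv`, `patients.csv` and optionally `overrides.csv`.
#' @param out_dir Output directory (created if needed).
#' @param priority Reconciliation source priority.
#' @param quiet Suppress per-stage log messages.
#' @return The [summarize_pipeline()] summary, invisibly.
#' @export
run_pipeline <- function(kb, cohort, out_dir, priority = .default_priority,
                         quiet = FALSE) {
  log <- function(...) if (!quiet) message(sprintf(...))
  if (is.character(kb)) { log("loading knowledge base from %s", kb); kb <- kb_load(kb) }
  if (is.character(cohort)) { log("loading cohort from %s", cohort); cohort <- cohort_read(cohort) }
  sources <- cohort$sources
  patients <- cohort$patients
  overrides <- cohort$overrides
  log("reconciling %d source records", nrow(sources))
  coh <- reconcile(sources, patients, priority)
  log("reconciled to %d medications in %d patients",
      nrow(coh$medications), nrow(coh$patients))
  rev <- review_report(coh, kb)
  log("review: %d/%d patients with DDI, %d/%d aged 65+ with PIM",
      rev$n_with_ddi, rev$n_assessable, rev$n_with_pim, rev$n_aged_65plus)
  decisions <- switch_cohort(coh, kb, overrides)
  log("switching: %s",
      paste(sprintf("%s=%d", .status_levels,
                    vapply(.status_levels, function(s) sum(decisions$status == s),
                           integer(1L))), collapse = " "))
  ord <- build_order_list(decisions)
  summary <- summarize_pipeline(decisions, coh, rev)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dcsv <- decisions[, c("patient_id", "med_id", "product_name", "ingredients",
                        "status", "targets_chr", "channel", "rationale")]
  names(dcsv)[names(dcsv) == "targets_chr"] <- "targets"
  utils::write.csv(dcsv, file.path(out_dir, "decisions.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  utils::write.csv(ord$orders, file.path(out_dir, "orders.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  utils::write.csv(ord$needs_information,
                   file.path(out_dir, "needs_information.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  fr <- rbind(
    if (nrow(rev$ddi_findings)) data.frame(
      patient_id = rev$ddi_findings$patient_id, type = "ddi",
      detail_1 = rev$ddi_findings$ingredient_a,
      detail_2 = rev$ddi_findings$ingredient_b,
      detail_3 = rev$ddi_findings$severity, stringsAsFactors = FALSE),
    if (nrow(rev$pim_findings)) data.frame(
      patient_id = rev$pim_findings$patient_id, type = "pim",
      detail_1 = rev$pim_findings$ingredient,
      detail_2 = rev$pim_findings$catalog,
      detail_3 = rev$pim_findings$category, stringsAsFactors = FALSE))
  if (is.null(fr)) fr <- data.frame(patient_id = character(), type = character(),
                                    detail_1 = character(), detail_2 = character(),
                                    detail_3 = character(), stringsAsFactors = FALSE)
  utils::write.csv(fr, file.path(out_dir, "review_findings.csv"),
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  jsonlite::write_json(unclass(summary), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  writeLines(.summary_md(summary), file.path(out_dir, "summary.md"))
  log("artifacts written to %s", out_dir)
  invisible(summary)
}

.summary_md <- function(s) {
  st <- s$status_table
  c("# Switching summary", "",
    sprintf("- Patients: %d", s$n_patients),
    sprintf("- Medications: %d (%d active ingredients)",
            s$n_medications, s$n_active_ingredients),
    sprintf("- Medications per patient: median %g (Q25 %g, Q75 %g)",
            s$medications_per_patient$median, s$medications_per_patient$q25,
            s$medications_per_patient$q75), "",
    "| Status | n | % |", "|---|---|---|",
    sprintf("| %s | %d | %.1f |", st$status, st$n, st$pct), "",
    sprintf("Combination products: %d; switched to mono-products: %d (%.1f%%), resolved as combination products: %d (%.1f%%)",
            s$combination_products$n, s$combination_products$switched_to_mono,
            s$combination_products$pct_mono,
            s$combination_products$resolved_as_combination,
            s$combination_products$pct_combination),
    if (!is.null(s$review))
      sprintf("Review: DDI in %d/%d assessable patients (%.1f%%); PIM in %d/%d patients aged 65+ (%.1f%%)",
              s$review$n_with_ddi, s$review$n_assessable, s$review$pct_ddi,
              s$review$n_with_pim, s$review$n_aged_65plus, s$review$pct_pim))
}
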