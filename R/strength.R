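# Ingredient names, strength units and component multisets.
#
# A medication or product is described by one or more components, each an
# ingredient key (normalized name + optional salt) with a strength
# (amount + unit). Strength comparison happens only after normalization to a
# canonical base unit: all masses to mg, mass/volume to mg/ml; international
# units (iu, iu/ml) are kept as their own dimension and never compared with
# masses. Components are compared as multisets via a canonical signature
# string.

#' Normalize an ingredient name
#'
#' Lower-cases, trims and collapses whitespace, then applies a synonym map
#' (e.g. albuterol -> salbutamol) so that alternate names compare equal.
#'
#' @param x Character vector of ingredient names.
#' @param synonyms Named character vector mapping alias -> canonical name.
#'   Defaults to the packaged map ([default_synonyms()]).
#' @return Character vector of normalized names.
#' @export
norm_ingredient <- function(x, synonyms = default_synonyms()) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  hit <- match(x, names(synonyms))
  x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  x
}

#' Packaged ingredient synonym map
#'
#' Symmetric lookup is obtained by normalizing both sides of a comparison;
#' the map itself stores alias -> canonical.
#' @return Named character vector.
#' @export
default_synonyms <- function() {
  c(albuterol = "salbutamol",
    metamizole = "dipyrone",
    acetaminophen = "paracetamol",
    levothyroxine = "l-thyroxine")
}

# unit table: canonical unit and multiplicative factor into it
.unit_table <- list(
  mg      = list(unit = "mg",    factor = 1),
  g       = list(unit = "mg",    factor = 1000),
  mcg     = list(unit = "mg",    factor = 0.001),
  ug      = list(unit = "mg",    factor = 0.001),
  "µg" = list(unit = "mg",  factor = 0.001),
  "mg/ml" = list(unit = "mg/ml", factor = 1),
  "g/l"   = list(unit = "mg/ml", factor = 1),
  "mcg/ml" = list(unit = "mg/ml", factor = 0.001),
  iu      = list(unit = "iu",    factor = 1),
  "iu/ml" = list(unit = "iu/ml", factor = 1)
)

#' Normalize a strength to its canonical base unit
#'
#' @param amount Numeric vector (NA for unknown strength).
#' @param unit Character vector of units (mg, g, mcg, mg/ml, iu, iu/ml, ...).
#'   Unknown units are kept verbatim (they only ever compare with themselves).
#' @return A data.frame with columns `qty` (canonical amount) and `qunit`.
#' @export
normalize_strength <- function(amount, unit) {
  unit <- tolower(trimws(unit))
  qty <- as.numeric(amount)
  qunit <- unit
  for (i in seq_along(qty)) {
    if (!is.na(unit[i]) && unit[i] %in% names(.unit_table)) {
      u <- .unit_table[[unit[i]]]
      qty[i] <- qty[i] * u$factor
      qunit[i] <- u$unit
    }
  }
  if (any(!is.na(qty) & qty <= 0))
    stop("strength amounts must be positive", call. = FALSE)
  data.frame(qty = qty, qunit = qunit, stringsAsFactors = FALSE)
}

#' Parse a component specification string
#'
#' The textual interchange format for component lists is
#' `"ingredient[|salt]:amount unit"` with multiple components joined by
#' semicolons, e.g. `"candesartan:16 mg;hydrochlorothiazide:12.5 mg"` or
#' `"metoprolol|succinate:95 mg"`. A missing strength is written `":NA"`
#' (or an empty amount).
#'
#' @param spec A single specification string (NA allowed -> zero components).
#' @param synonyms Synonym map passed to [norm_ingredient()].
#' @return A component data.frame with columns ingredient, salt, amount,
#'   unit, qty, qunit.
#' @export
parse_components <- function(spec, synonyms = default_synonyms()) {
  empty <- data.frame(ingredient = character(), salt = character(),
                      amount = numeric(), unit = character(),
                      qty = numeric(), qunit = character(),
                      stringsAsFactors = FALSE)
  if (length(spec) != 1L) stop("parse_components() takes one spec string")
  if (is.na(spec) || !nzchar(trimws(spec))) return(empty)
  parts <- strsplit(spec, ";", fixed = TRUE)[[1L]]
  rows <- lapply(parts, function(p) {
    p <- trimws(p)
    colon <- regexpr(":", p, fixed = TRUE)
    if (colon < 0) { name_part <- p; strength_part <- NA_character_ }
    else {
      name_part <- substr(p, 1L, colon - 1L)
      strength_part <- trimws(substr(p, colon + 1L, nchar(p)))
    }
    np <- strsplit(name_part, "|", fixed = TRUE)[[1L]]
    ingredient <- norm_ingredient(np[1L], synonyms)
    salt <- if (length(np) > 1L && nzchar(trimws(np[2L])))
      tolower(trimws(np[2L])) else NA_character_
    if (!nzchar(ingredient))
      stop(sprintf("component '%s': empty ingredient name", p), call. = FALSE)
    amount <- NA_real_; unit <- NA_character_
    if (!is.na(strength_part) && nzchar(strength_part) &&
        !toupper(strength_part) %in% c("NA", "?")) {
      m <- regmatches(strength_part,
                      regexec("^([0-9.]+)[[:space:]]*(.*)$", strength_part))[[1L]]
      if (length(m) != 3L || !nzchar(m[2L]))
        stop(sprintf("component '%s': cannot parse strength '%s'", p, strength_part),
             call. = FALSE)
      amount <- as.numeric(m[2L])
      unit <- if (nzchar(m[3L])) tolower(m[3L]) else "mg"
    }
    data.frame(ingredient = ingredient, salt = salt, amount = amount,
               unit = unit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(paste(out$ingredient, out$salt, sep = "\r")))
    stop("duplicate ingredient within one component list: ", spec, call. = FALSE)
  ns <- normalize_strength(out$amount, out$unit)
  out$qty <- ns$qty
  out$qunit <- ns$qunit
  out
}

#' Serialize a component data.frame back to its specification string
#' @param comps A component data.frame as returned by [parse_components()].
#' @return A single string.
#' @export
format_components <- function(comps) {
  if (nrow(comps) == 0L) return("")
  paste(vapply(seq_len(nrow(comps)), function(i) {
    key <- comps$ingredient[i]
    if (!is.na(comps$salt[i])) key <- paste0(key, "|", comps$salt[i])
    s <- if (is.na(comps$amount[i])) "NA"
         else paste(format(comps$amount[i], scientific = FALSE, trim = TRUE),
                    comps$unit[i])
    paste0(key, ":", s)
  }, character(1L)), collapse = ";")
}

# Canonical multiset signature of a component list. Two products / meds have
# equal active content iff their signatures are equal. NA strengths yield an
# NA signature (content not comparable).
component_signature <- function(comps) {
  if (nrow(comps) == 0L) return(NA_character_)
  if (any(is.na(comps$qty))) return(NA_character_)
  keys <- sprintf("%s|%s#%.10g%s",
                  comps$ingredient,
                  ifelse(is.na(comps$salt), "", comps$salt),
                  comps$qty, comps$qunit)
  paste(sort(keys), collapse = "+")
}

# signature ignoring strengths (identity of the ingredient multiset)
ingredient_signature <- function(comps) {
  if (nrow(comps) == 0L) return(NA_character_)
  keys <- sprintf("%s|%s", comps$ingredient,
                  ifelse(is.na(comps$salt), "", comps$salt))
  paste(sort(keys), collapse = "+")
}
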