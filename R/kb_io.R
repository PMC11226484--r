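# Reading and writing knowledge-base tables as UTF-8 CSV files, validated
# against the JSON schema files shipped under inst/extdata/schemas.

.kb_files <- c(formulary = "formulary.csv",
               exclusion = "exclusion_list.csv",
               equivalence = "equivalence.csv",
               interactions = "interactions.csv",
               pim = "pim.csv",
               synonyms = "synonyms.csv",
               form_classes = "form_classes.csv")

.read_kb_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  colClasses = "character", fileEncoding = "UTF-8")
}

# validate a raw character data.frame against one packaged JSON schema
validate_table <- function(df, schema_name, file = schema_name) {
  schema_path <- system.file("extdata", "schemas",
                             paste0(schema_name, ".schema.json"),
                             package = "switchrx")
  if (!nzchar(schema_path))
    stop("schema not found: ", schema_name, call. = FALSE)
  schema <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  for (col in schema$columns) {
    nm <- col$name
    if (isTRUE(col$required) && !nm %in% names(df))
      stop(sprintf("%s: required column '%s' missing", file, nm), call. = FALSE)
    if (!nm %in% names(df)) next
    vals <- df[[nm]]
    if (col$type %in% c("number", "integer")) {
      num <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & is.na(num))
      if (length(bad))
        stop(sprintf("%s: column '%s', row %d: '%s' is not numeric",
                     file, nm, bad[1L], vals[bad[1L]]), call. = FALSE)
      df[[nm]] <- if (col$type == "integer") as.integer(num) else num
    } else if (col$type == "boolean") {
      lg <- toupper(trimws(vals)) %in% c("TRUE", "T", "1", "YES")
      lg[is.na(vals)] <- NA
      df[[nm]] <- lg
    }
    if (isTRUE(col$required)) {
      bad <- which(is.na(df[[nm]]))
      if (length(bad))
        stop(sprintf("%s: column '%s', row %d: missing required value",
                     file, nm, bad[1L]), call. = FALSE)
    }
    if (!is.null(col$enum)) {
      allowed <- unlist(col$enum)
      bad <- which(!is.na(df[[nm]]) & !tolower(df[[nm]]) %in% tolower(allowed))
      if (length(bad))
        stop(sprintf("%s: column '%s', row %d: '%s' not one of %s",
                     file, nm, bad[1L], df[[nm]][bad[1L]],
                     paste(allowed, collapse = "/")), call. = FALSE)
    }
  }
  df
}

#' Load a knowledge base from a directory of CSV tables
#'
#' Expects `formulary.csv`, and optionally `exclusion_list.csv`,
#' `equivalence.csv`, `interactions.csv`, `pim.csv`, `synonyms.csv`,
#' `form_classes.csv` (see the schema files under
#' `system.file("extdata", "schemas", package = "switchrx")` for the column
#' contracts). Missing optional tables fall back to packaged defaults
#' (exclusion list, synonym map) or to empty tables. Every table is validated
#' against its schema; violations raise an error naming file and row.
#'
#' @param dir Directory containing the CSV files.
#' @return A [knowledge_base()].
#' @export
kb_load <- function(dir) {
  p <- function(key) file.path(dir, .kb_files[[key]])
  if (!file.exists(p("formulary")))
    stop("knowledge base file not found: ", p("formulary"), call. = FALSE)
  read1 <- function(key) {
    if (!file.exists(p(key))) return(NULL)
    validate_table(.read_kb_csv(p(key)), key, .kb_files[[key]])
  }
  fm <- read1("formulary")
  syn_df <- read1("synonyms")
  synonyms <- if (is.null(syn_df) || nrow(syn_df) == 0L) default_synonyms()
              else stats::setNames(tolower(syn_df$canonical), tolower(syn_df$alias))
  fc_df <- read1("form_classes")
  form_classes <- if (is.null(fc_df) || nrow(fc_df) == 0L) character()
                  else stats::setNames(tolower(fc_df$class), tolower(fc_df$form))
  knowledge_base(formulary = formulary(fm, synonyms),
                 exclusion = read1("exclusion"),
                 equivalence = read1("equivalence"),
                 interactions = read1("interactions"),
                 pim = read1("pim"),
                 synonyms = synonyms,
                 form_classes = form_classes)
}

#' Write a knowledge base to a directory of CSV tables
#'
#' Inverse of [kb_load()]: loading, writing, then reloading yields an
#' identical knowledge base.
#'
#' @param kb A [knowledge_base()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
kb_write <- function(kb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, key) utils::write.csv(df, file.path(dir, .kb_files[[key]]),
                                          row.names = FALSE, na = "",
                                          fileEncoding = "UTF-8")
  fm <- as.data.frame(kb$formulary)[, c("product_name", "dosage_form", "atc",
                                        "components")]
  w(fm, "formulary")
  w(kb$exclusion, "exclusion")
  eq <- kb$equivalence[, c("table_id", "source_ingredient", "source_strength",
                           "target_ingredient", "target_strength", "match_level")]
  w(eq, "equivalence")
  w(kb$interactions, "interactions")
  w(kb$pim, "pim")
  w(data.frame(alias = as.character(names(kb$synonyms)),
               canonical = as.character(unname(kb$synonyms)),
               stringsAsFactors = FALSE), "synonyms")
  w(data.frame(form = as.character(names(kb$form_classes)),
               class = as.character(unname(kb$form_classes)),
               stringsAsFactors = FALSE), "form_classes")
  invisible(dir)
}
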