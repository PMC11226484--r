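#' Parse and validate an ATC code
#'
#' The WHO Anatomical-Therapeutic-Chemical classification assigns drugs a
#' 7-character code built from five nested levels: anatomical main group
#' (1 letter), therapeutic subgroup (2 digits), pharmacological subgroup
#' (1 letter), chemical subgroup (1 letter), and chemical substance
#' (2 digits). Valid codes are therefore 1, 3, 4, 5 or 7 characters long,
#' e.g. `"A"`, `"A10"`, `"A10B"`, `"A10BA"`, `"A10BA02"`.
#'
#' @param code A single non-empty character string.
#' @return An object of class `atc_code`: the upper-cased code string with
#'   attributes `level` (1-5) and `prefixes` (the codes of all shallower
#'   levels).
#' @examples
#' x <- parse_atc("A10BA02")
#' atc_level(x)        # 5
#' attr(x, "prefixes") # "A" "A10" "A10B" "A10BA"
#' @export
parse_atc <- function(code) {
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code))
    stop("ATC code must be a single non-empty string", call. = FALSE)
  code <- toupper(trimws(code))
  len <- nchar(code)
  lens <- c(1L, 3L, 4L, 5L, 7L)
  if (!len %in% lens)
    stop(sprintf("ATC code '%s': invalid length %d (must be 1, 3, 4, 5 or 7)",
                 code, len), call. = FALSE)
  # character classes alternate letter / digit-pair / letter / letter / digit-pair
  classes <- c("L", "D", "D", "L", "L", "D", "D")
  chars <- strsplit(code, "")[[1L]]
  for (i in seq_len(len)) {
    ok <- if (classes[i] == "L") grepl("^[A-Z]$", chars[i]) else grepl("^[0-9]$", chars[i])
    if (!ok)
      stop(sprintf("ATC code '%s': %s expected at position %d",
                   code, if (classes[i] == "L") "letter" else "digit", i),
           call. = FALSE)
  }
  level <- match(len, lens)
  structure(code,
            level = level,
            prefixes = vapply(lens[seq_len(level - 1L)],
                              function(k) substr(code, 1L, k), character(1L)),
            class = "atc_code")
}

#' @rdname parse_atc
#' @param x An `atc_code` or a string coercible to one.
#' @export
atc_level <- function(x) {
  if (!inherits(x, "atc_code")) x <- parse_atc(x)
  attr(x, "level")
}

# prefix length (in characters) of an ATC level
atc_prefix_len <- function(level) c(1L, 3L, 4L, 5L, 7L)[level]

#' Test whether two ATC codes agree at a classification level
#'
#' Two codes match at level `k` when their level-`k` prefixes are equal.
#' Matching is reflexive at any valid level and monotone: agreement at level
#' `k` implies agreement at every shallower level.
#'
#' @param a,b ATC codes (strings or `atc_code` objects).
#' @param level Integer in 1..5. Both codes must be at least this deep.
#' @return `TRUE` or `FALSE`.
#' @examples
#' atc_match("A10BA02", "A10BA01", 4) # TRUE
#' atc_match("A10BA02", "A10BA01", 5) # FALSE
#' @export
atc_match <- function(a, b, level) {
  if (!inherits(a, "atc_code")) a <- parse_atc(a)
  if (!inherits(b, "atc_code")) b <- parse_atc(b)
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L || level > 5L)
    stop("level must be an integer in 1..5", call. = FALSE)
  if (atc_level(a) < level || atc_level(b) < level)
    stop(sprintf("level %d requested but codes '%s' (level %d) and '%s' (level %d) are not both that deep",
                 level, unclass(a), atc_level(a), unclass(b), atc_level(b)),
         call. = FALSE)
  n <- atc_prefix_len(level)
  substr(unclass(a), 1L, n) == substr(unclass(b), 1L, n)
}
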