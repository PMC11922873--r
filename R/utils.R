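#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all display tables, so that
#' e.g. 2.145 renders as 2.15. Base R's `round()` rounds half to even.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percent of a denominator, display-rounded
#'
#' @param count numerator count(s)
#' @param denom denominator count(s)
#' @param digits decimal places (default 2, the table convention)
#' @return percent in `[0, 100]`, `NA` where the denominator is zero
#' @export
percent_of <- function(count, denom, digits = 2) {
  out <- round_half_up(100 * count / denom, digits)
  bad <- is.na(denom) | denom <= 0
  out[rep_len(bad, length(out))] <- NA_real_
  out
}

#' Canonicalize a MedDRA preferred term string
#'
#' Trims and collapses whitespace, lower-cases, then upper-cases the first
#' character, giving the sentence case MedDRA uses ("On and off phenomenon").
#' Term comparison throughout the package is on canonicalized strings.
#'
#' @param x character vector of raw term strings
#' @return canonicalized character vector
#' @export
canonical_pt <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  x <- tolower(x)
  first <- toupper(substr(x, 1L, 1L))
  out <- paste0(first, substr(x, 2L, nchar(x)))
  out[is.na(x) | x == ""] <- NA_character_
  out
}

# case-insensitive fixed-substring match of any pattern against one or more
# character vectors; returns logical the length of the first vector
match_any_pattern <- function(patterns, ...) {
  fields <- lapply(list(...), function(f) tolower(ifelse(is.na(f), "", f)))
  pats <- tolower(patterns)
  hit <- rep(FALSE, length(fields[[1L]]))
  for (p in pats) {
    for (f in fields) hit <- hit | grepl(p, f, fixed = TRUE)
  }
  hit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
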