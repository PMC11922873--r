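#' Path to a bundled dictionary file
#'
#' @param name file name under `inst/extdata/dictionaries`
#' @return absolute path
#' @keywords internal
dict_path <- function(name) {
  p <- system.file("extdata", "dictionaries", name, package = "faersignal")
  if (p == "") stop("bundled dictionary not found: ", name, call. = FALSE)
  p
}

read_dict <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Load the preferred-term to system-organ-class mapping
#'
#' A flat PT -> SOC table (miniature MedDRA stand-in, ~70 terms covering the
#' motor-complication endpoints and common co-reported events). Preferred
#' terms are canonicalized on load.
#'
#' @param path optional path to a user-supplied two-column TSV (`pt`, `soc`);
#'   defaults to the bundled dictionary
#' @return tibble with columns `pt`, `soc`
#' @export
load_pt_soc <- function(path = dict_path("pt_soc.tsv")) {
  d <- read_dict(path)
  stopifnot(all(c("pt", "soc") %in% names(d)))
  tibble::tibble(pt = canonical_pt(d$pt), soc = trimws(d$soc))
}

#' Load the composite motor-complication endpoint dictionary
#'
#' Each row maps one pattern to an endpoint. `match_mode` is either
#' `exact_pt` (whole-term match after canonicalization) or
#' `keyword_substring` (case-insensitive substring on the term). Validates
#' that no pattern is claimed by two endpoints and that no endpoint's
#' pattern would also match another endpoint's patterns (member sets must
#' be disjoint).
#'
#' @param path optional path to a TSV with columns `endpoint`, `pattern`,
#'   `match_mode`; defaults to the bundled dictionary
#' @return tibble with columns `endpoint`, `pattern`, `match_mode`
#' @export
load_endpoints <- function(path = dict_path("endpoints.tsv")) {
  d <- read_dict(path)
  stopifnot(all(c("endpoint", "pattern", "match_mode") %in% names(d)))
  if (any(!d$match_mode %in% c("exact_pt", "keyword_substring"))) {
    stop("endpoint dictionary: match_mode must be exact_pt or keyword_substring",
         call. = FALSE)
  }
  if (any(trimws(d$pattern) == "")) {
    stop("endpoint dictionary: empty pattern", call. = FALSE)
  }
  d$pattern_lc <- tolower(trimws(d$pattern))
  # disjointness: a pattern of one endpoint may not (substring-)match a
  # pattern of another
  eps <- unique(d$endpoint)
  for (e1 in eps) {
    for (e2 in setdiff(eps, e1)) {
      p1 <- d$pattern_lc[d$endpoint == e1]
      p2 <- d$pattern_lc[d$endpoint == e2]
      clash <- outer(p1, p2, function(a, b) {
        mapply(function(x, y) grepl(x, y, fixed = TRUE) || grepl(y, x, fixed = TRUE),
               a, b)
      })
      if (any(clash)) {
        stop("endpoint dictionary: overlapping member patterns between '",
             e1, "' and '", e2, "'", call. = FALSE)
      }
    }
  }
  tibble::as_tibble(d[, c("endpoint", "pattern", "match_mode")])
}

#' Load field-level normalization tables
#'
#' Route strings, reporter occupation codes, and reporter-country codes map
#' onto closed vocabularies through editable TSV files; unknown codes fall
#' back to `unknown` (routes, reporters) or `other` (countries) rather than
#' erroring.
#'
#' @name normalization-tables
#' @param path optional path to a replacement TSV
#' @return a named character lookup vector
NULL

#' @rdname normalization-tables
#' @export
load_route_map <- function(path = dict_path("routes.tsv")) {
  d <- read_dict(path)
  stats::setNames(d$canonical, toupper(trimws(d$raw)))
}

#' @rdname normalization-tables
#' @export
load_reporter_map <- function(path = dict_path("reporters.tsv")) {
  d <- read_dict(path)
  stats::setNames(d$label, toupper(trimws(d$code)))
}

#' @rdname normalization-tables
#' @export
load_country_map <- function(path = dict_path("countries.tsv")) {
  d <- read_dict(path)
  stats::setNames(d$group, toupper(trimws(d$code)))
}

#' Load the Parkinson's-disease indication term family
#'
#' @param path optional path to a one-column TSV (`pt`)
#' @return character vector of canonicalized preferred terms
#' @export
load_pd_indications <- function(path = dict_path("pd_indications.tsv")) {
  canonical_pt(read_dict(path)$pt)
}

#' Load the dementia/psychosis exclusion pattern family
#'
#' Case-insensitive substrings; any reaction or indication term matching one
#' of these excludes the report from the screened cohorts.
#'
#' @param path optional path to a one-column TSV (`pattern`)
#' @return character vector of lower-case substrings
#' @export
load_exclusion_patterns <- function(path = dict_path("exclusion_patterns.tsv")) {
  tolower(trimws(read_dict(path)$pattern))
}

#' Load the anti-parkinsonian drug dictionary used for concomitant ranking
#'
#' @param path optional path to a one-column TSV (`drug`)
#' @return character vector of lower-case drug names
#' @export
load_anti_pd_drugs <- function(path = dict_path("anti_pd_drugs.tsv")) {
  tolower(trimws(read_dict(path)$drug))
}

#' Default whitelist of system organ classes for motor-complication screening
#'
#' Nervous system disorders plus general disorders and administration site
#' conditions: the two SOCs housing motor fluctuation and dyskinesia terms.
#'
#' @return character vector of SOC names
#' @export
default_soc_whitelist <- function() {
  c("Nervous system disorders",
    "General disorders and administration site conditions")
}
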