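# Composite motor-complication endpoints. The on-off and freezing
# phenomena have their own preferred terms in MedDRA and are matched
# exactly; dyskinesia and wearing-off are composites reclassified from a
# keyword family (dyskinesia, dystonia, hyperkinesia, ballismus, alien limb
# syndrome; incomplete/shortened therapeutic response), matched as
# lower-case substrings of the term.

#' Map reaction terms to composite motor-complication endpoints
#'
#' Operates on a reaction table (one row per case x term). A case carries
#' an endpoint when at least one of its terms matches a member pattern of
#' that endpoint; it contributes at most once per endpoint regardless of
#' how many member terms it lists. Every hit is traceable: the matching
#' terms are kept in `matched_pts`.
#'
#' @param reactions tibble with columns `case_id`, `pt` — typically a
#'   cohort's [analysis_reactions()], or the full reaction table of a
#'   comparator set
#' @param endpoints endpoint dictionary from [load_endpoints()]
#' @return tibble with columns `case_id`, `endpoint`, `matched_pts`
#'   (matching terms collapsed with `"; "`), one row per case x endpoint
#' @export
map_endpoints <- function(reactions, endpoints = load_endpoints()) {
  if (nrow(reactions) == 0L) {
    return(tibble::tibble(case_id = character(), endpoint = character(),
                          matched_pts = character()))
  }
  pts <- reactions$pt
  pts_lc <- tolower(pts)
  hits <- lapply(unique(endpoints$endpoint), function(e) {
    sub <- endpoints[endpoints$endpoint == e, , drop = FALSE]
    hit <- rep(FALSE, length(pts))
    for (i in seq_len(nrow(sub))) {
      if (sub$match_mode[[i]] == "exact_pt") {
        hit <- hit | pts == canonical_pt(sub$pattern[[i]])
      } else {
        hit <- hit | grepl(tolower(sub$pattern[[i]]), pts_lc, fixed = TRUE)
      }
    }
    if (!any(hit)) return(NULL)
    d <- tibble::tibble(case_id = reactions$case_id[hit], pt = pts[hit])
    d <- dplyr::distinct(d)
    d |>
      dplyr::group_by(.data$case_id) |>
      dplyr::summarise(matched_pts = paste(sort(.data$pt), collapse = "; "),
                       .groups = "drop") |>
      dplyr::mutate(endpoint = e)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(case_id = character(), endpoint = character(),
                          matched_pts = character()))
  }
  out[, c("case_id", "endpoint", "matched_pts")]
}

#' Endpoint hit counts for a set of cases
#'
#' @param reactions reaction table (`case_id`, `pt`)
#' @param endpoints endpoint dictionary
#' @return named integer vector of case counts per endpoint (all endpoints
#'   present, zeros included)
#' @export
endpoint_counts <- function(reactions, endpoints = load_endpoints()) {
  m <- map_endpoints(reactions, endpoints)
  eps <- unique(endpoints$endpoint)
  cnt <- table(factor(m$endpoint, levels = eps))
  stats::setNames(as.integer(cnt), eps)
}
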