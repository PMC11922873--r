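# Screening cascade: suspect-drug match -> oral route -> PD indication and
# exclusion terms -> system-organ-class restriction. Every filter is a pure
# predicate on one case, so the terminal cohort does not depend on stage
# order; only the trace does.

#' Define a drug cohort query
#'
#' A query retains cases that carry at least one drug entry whose verbatim
#' name or active-ingredient string contains one of `name_patterns`
#' (case-insensitive substring; covers brand and generic names) with a role
#' in `required_roles`, and at least one entry (possibly the same row, as
#' for combination products) matching `required_partner_patterns` with a
#' role in `required_roles`.
#'
#' @param target_label short cohort label, e.g. `"BSZ"`
#' @param name_patterns character vector of target-drug substrings
#' @param required_partner_patterns substrings that must also appear among
#'   the case's suspect drugs (the levodopa partner); may be empty to
#'   disable the partner requirement
#' @param required_roles drug roles accepted as "suspect"; default primary
#'   and secondary suspects
#' @return a `drug_query` object
#' @export
drug_query <- function(target_label, name_patterns,
                       required_partner_patterns = "levodopa",
                       required_roles = c("suspect_primary",
                                          "suspect_secondary")) {
  if (length(name_patterns) == 0L || any(!nzchar(name_patterns))) {
    stop("drug_query: name_patterns must be non-empty", call. = FALSE)
  }
  structure(list(target_label = target_label,
                 name_patterns = name_patterns,
                 required_partner_patterns = required_partner_patterns,
                 required_roles = required_roles),
            class = "drug_query")
}

#' Benserazide and carbidopa cohort queries
#'
#' Default queries for the two dopa-decarboxylase inhibitors co-formulated
#' with levodopa, with common brand names included.
#'
#' @return named list of two [drug_query()] objects (`BSZ`, `CD`)
#' @export
default_drug_queries <- function() {
  list(
    BSZ = drug_query("BSZ", c("benserazide", "madopar", "prolopa")),
    CD = drug_query("CD", c("carbidopa", "sinemet", "lodosyn", "duopa",
                            "rytary", "stalevo"))
  )
}

# drug rows of `cases` matching a pattern set within the allowed roles;
# returns tibble(case_id, drug_seq, route)
query_matched_rows <- function(cases, patterns, roles) {
  d <- cases$drugs
  hit <- match_any_pattern(patterns, d$name_raw, d$active_ingredient) &
    d$role %in% roles
  d[hit, c("case_id", "drug_seq", "route"), drop = FALSE]
}

#' Select the reports matching a drug cohort query
#'
#' @param cases a deduplicated `faers_cases` object
#' @param query a [drug_query()]
#' @return the matching subset of `cases`, with attribute `matches`: a
#'   tibble of the matched target/partner drug rows (`case_id`, `drug_seq`,
#'   `route`, `which`)
#' @export
select_drug_reports <- function(cases, query) {
  stopifnot(inherits(query, "drug_query"))
  tgt <- query_matched_rows(cases, query$name_patterns, query$required_roles)
  if (length(query$required_partner_patterns) > 0L) {
    par <- query_matched_rows(cases, query$required_partner_patterns,
                              query$required_roles)
    ids <- intersect(unique(tgt$case_id), unique(par$case_id))
  } else {
    par <- tgt[0L, , drop = FALSE]
    ids <- unique(tgt$case_id)
  }
  matches <- dplyr::bind_rows(
    dplyr::mutate(tgt[tgt$case_id %in% ids, , drop = FALSE], which = "target"),
    dplyr::mutate(par[par$case_id %in% ids, , drop = FALSE], which = "partner")
  )
  out <- subset_cases(cases, ids)
  attr(out, "matches") <- matches
  out
}

# cases for which >=1 matched target row and (when present) >=1 matched
# partner row have the given canonical route
matched_route_ok <- function(matches, route_value = "oral") {
  ok_by <- function(w) {
    m <- matches[matches$which == w, , drop = FALSE]
    ids_all <- unique(m$case_id)
    ids_ok <- unique(m$case_id[m$route == route_value])
    list(all = ids_all, ok = ids_ok)
  }
  t <- ok_by("target"); p <- ok_by("partner")
  ok <- t$ok
  if (length(p$all) > 0L) ok <- intersect(ok, p$ok)
  ok
}

#' Restrict a matched cohort to oral administration
#'
#' Retains cases whose matched target entry (and matched levodopa partner
#' entry, when a partner is required) has canonical route `oral`. The test
#' applies to the matched entries only, not to every drug in the case;
#' unknown routes are excluded (conservative reading of an oral-only
#' inclusion rule). Requires the `matches` attribute set by
#' [select_drug_reports()].
#'
#' @param cases output of [select_drug_reports()]
#' @return filtered `faers_cases` with updated `matches` attribute
#' @export
filter_oral_route <- function(cases) {
  matches <- attr(cases, "matches")
  if (is.null(matches)) {
    stop("filter_oral_route: run select_drug_reports() first", call. = FALSE)
  }
  ids <- matched_route_ok(matches, "oral")
  out <- subset_cases(cases, ids)
  attr(out, "matches") <- matches[matches$case_id %in% ids, , drop = FALSE]
  out
}

#' Restrict to Parkinson's disease as indication, with exclusions
#'
#' Retains cases that (i) carry a Parkinson's-disease indication term
#' attached to a matched target/partner drug entry (indication rows with no
#' drug link count case-wide), (ii) do not list a Parkinson's-disease term
#' among the reactions, and (iii) have no dementia/psychosis-family term
#' among reactions or indications.
#'
#' @param cases output of [select_drug_reports()] (or a later filter)
#' @param pd_terms canonical PD indication terms; default bundled family
#' @param exclusion_patterns lower-case substrings excluding a case when
#'   found in any reaction or indication term
#' @return filtered `faers_cases` with updated `matches` attribute
#' @export
filter_indication <- function(cases,
                              pd_terms = load_pd_indications(),
                              exclusion_patterns = load_exclusion_patterns()) {
  matches <- attr(cases, "matches")
  if (is.null(matches)) {
    stop("filter_indication: run select_drug_reports() first", call. = FALSE)
  }
  ind <- cases$indications
  matched_key <- paste(matches$case_id, matches$drug_seq)
  linked <- is.na(ind$drug_seq) |
    paste(ind$case_id, ind$drug_seq) %in% matched_key
  pd_ok_ids <- unique(ind$case_id[linked & ind$pt %in% pd_terms])

  reac <- cases$reactions
  pd_as_reaction <- unique(reac$case_id[reac$pt %in% pd_terms])

  excl_hit <- function(tb) {
    if (nrow(tb) == 0L) return(character(0))
    unique(tb$case_id[match_any_pattern(exclusion_patterns, tb$pt)])
  }
  excluded <- union(excl_hit(reac), excl_hit(ind))

  ids <- setdiff(setdiff(pd_ok_ids, pd_as_reaction), excluded)
  out <- subset_cases(cases, ids)
  attr(out, "matches") <- matches[matches$case_id %in% ids, , drop = FALSE]
  out
}

#' Restrict to reports with events in whitelisted system organ classes
#'
#' Retains cases with at least one reaction term whose SOC is whitelisted.
#' Reactions outside the whitelist are masked from the analysis view
#' (attribute `analysis_reactions`) but preserved in the case set itself.
#' Terms absent from the PT->SOC mapping are treated as non-whitelisted and
#' counted in a message.
#'
#' @param cases a `faers_cases` object
#' @param soc_whitelist SOC names to keep; default [default_soc_whitelist()]
#' @param pt_soc PT->SOC mapping tibble; default bundled dictionary
#' @return filtered `faers_cases` with attribute `analysis_reactions` (a
#'   tibble `case_id`, `pt`, `soc`) and the `matches` attribute carried over
#' @export
filter_soc <- function(cases, soc_whitelist = default_soc_whitelist(),
                       pt_soc = load_pt_soc()) {
  matches <- attr(cases, "matches")
  reac <- cases$reactions
  soc <- pt_soc$soc[match(reac$pt, pt_soc$pt)]
  unmapped <- is.na(soc) & !is.na(reac$pt)
  if (any(unmapped)) {
    message("filter_soc: ", sum(unmapped),
            " reaction term occurrence(s) absent from the PT->SOC mapping; ",
            "treated as non-whitelisted")
  }
  keep <- !is.na(soc) & soc %in% soc_whitelist
  analysis <- tibble::tibble(case_id = reac$case_id[keep],
                             pt = reac$pt[keep], soc = soc[keep])
  ids <- unique(analysis$case_id)
  out <- subset_cases(cases, ids)
  if (!is.null(matches)) {
    attr(out, "matches") <- matches[matches$case_id %in% ids, , drop = FALSE]
  }
  attr(out, "analysis_reactions") <-
    analysis[analysis$case_id %in% ids, , drop = FALSE]
  out
}

#' Screening cascade configuration
#'
#' @param queries named list of [drug_query()] objects; default the
#'   benserazide/carbidopa pair
#' @param soc_whitelist SOC whitelist
#' @param pt_soc PT->SOC mapping tibble
#' @param pd_terms PD indication term family
#' @param exclusion_patterns dementia/psychosis exclusion substrings
#' @param stages logical toggles for the three post-match filters
#' @param drop_dual drop cases matching more than one query from all
#'   cohorts (default FALSE: retained in each and flagged)
#' @return a `screening_config` object
#' @export
screening_config <- function(queries = default_drug_queries(),
                             soc_whitelist = default_soc_whitelist(),
                             pt_soc = load_pt_soc(),
                             pd_terms = load_pd_indications(),
                             exclusion_patterns = load_exclusion_patterns(),
                             stages = c(oral_route = TRUE,
                                        pd_indication = TRUE, soc = TRUE),
                             drop_dual = FALSE) {
  stopifnot(length(queries) >= 1L,
            all(vapply(queries, inherits, logical(1), "drug_query")))
  structure(list(queries = queries, soc_whitelist = soc_whitelist,
                 pt_soc = pt_soc, pd_terms = pd_terms,
                 exclusion_patterns = exclusion_patterns,
                 stages = stages, drop_dual = drop_dual),
            class = "screening_config")
}

new_trace <- function(stages, counts) {
  structure(tibble::tibble(stage = stages, count = as.integer(counts)),
            class = c("screening_trace", "tbl_df", "tbl", "data.frame"))
}

#' Run the full screening cascade
#'
#' Applies, per query: drug match, oral-route restriction, PD
#' indication/exclusion filter, SOC restriction — in that order — and
#' records surviving case counts after each stage. The combined trace
#' counts cases surviving under at least one query at each stage.
#'
#' @param cases a deduplicated `faers_cases` object
#' @param config a [screening_config()]
#' @return list with `cohorts` (named list of `faers_cohort` objects, each
#'   carrying `label`, `cases`, `trace`, `dual` flag vector) and `trace`
#'   (combined `screening_trace`)
#' @export
run_cascade <- function(cases, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  on_stage <- function(name) isTRUE(config$stages[[name]])
  per_query <- lapply(config$queries, function(q) {
    stage_names <- "input"
    stage_sets <- list(unique(cases$demo$case_id))
    cur <- select_drug_reports(cases, q)
    stage_names <- c(stage_names, "drug_match")
    stage_sets <- c(stage_sets, list(cur$demo$case_id))
    if (on_stage("oral_route")) {
      cur <- filter_oral_route(cur)
      stage_names <- c(stage_names, "oral_route")
      stage_sets <- c(stage_sets, list(cur$demo$case_id))
    }
    if (on_stage("pd_indication")) {
      cur <- filter_indication(cur, config$pd_terms,
                               config$exclusion_patterns)
      stage_names <- c(stage_names, "pd_indication")
      stage_sets <- c(stage_sets, list(cur$demo$case_id))
    }
    if (on_stage("soc")) {
      cur <- filter_soc(cur, config$soc_whitelist, config$pt_soc)
      stage_names <- c(stage_names, "soc")
      stage_sets <- c(stage_sets, list(cur$demo$case_id))
    }
    list(cases = cur, stage_names = stage_names, stage_sets = stage_sets)
  })

  labels <- vapply(config$queries, `[[`, character(1), "target_label")
  terminal <- lapply(per_query, function(x) unique(x$cases$demo$case_id))
  all_ids <- unlist(terminal)
  dual_ids <- unique(all_ids[duplicated(all_ids)])

  cohorts <- stats::setNames(vector("list", length(per_query)), labels)
  for (i in seq_along(per_query)) {
    pq <- per_query[[i]]
    cas <- pq$cases
    if (config$drop_dual && length(dual_ids) > 0L) {
      keep <- setdiff(cas$demo$case_id, dual_ids)
      ar <- attr(cas, "analysis_reactions")
      mt <- attr(cas, "matches")
      cas <- subset_cases(cas, keep)
      if (!is.null(ar)) {
        attr(cas, "analysis_reactions") <- ar[ar$case_id %in% keep, ,
                                              drop = FALSE]
      }
      if (!is.null(mt)) {
        attr(cas, "matches") <- mt[mt$case_id %in% keep, , drop = FALSE]
      }
    }
    cohorts[[i]] <- structure(
      list(label = labels[[i]], cases = cas,
           trace = new_trace(pq$stage_names, lengths(pq$stage_sets)),
           dual = cas$demo$case_id %in% dual_ids),
      class = "faers_cohort")
  }

  stage_names <- per_query[[1L]]$stage_names
  combined <- vapply(seq_along(stage_names), function(k) {
    length(unique(unlist(lapply(per_query, function(x) x$stage_sets[[k]]))))
  }, integer(1))
  list(cohorts = cohorts, trace = new_trace(stage_names, combined))
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat(sprintf("<faers_cohort> %s: %d cases\n", x$label, n_cases(x$cases)))
  print(as.data.frame(x$trace), row.names = FALSE)
  invisible(x)
}

#' Analysis-view reactions of a cohort
#'
#' The SOC-whitelisted reaction terms of a screened cohort (one row per
#' case x term occurrence), as produced by [filter_soc()]. Falls back to
#' all reactions when the SOC stage was disabled.
#'
#' @param cohort a `faers_cohort` or a `faers_cases` with the
#'   `analysis_reactions` attribute
#' @return tibble `case_id`, `pt` (and `soc` when available)
#' @export
analysis_reactions <- function(cohort) {
  cas <- if (inherits(cohort, "faers_cohort")) cohort$cases else cohort
  ar <- attr(cas, "analysis_reactions")
  if (is.null(ar)) cas$reactions else ar
}
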