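# Descriptive tables with the study's percent-denominator conventions.
# Denominators differ by block: cohort size for age/reporter/sex/country,
# but the serious-outcomes block uses the sum of outcome-category counts
# (a case may carry several outcome codes and each code is counted), which
# reproduces e.g. hospitalization 906 / (906+649+353+50+1) = 46.25%.

freq_block <- function(variable, levels, counts, denominator) {
  stopifnot(length(levels) == length(counts))
  tibble::tibble(variable = variable, level = levels,
                 count = as.integer(counts),
                 denominator = as.integer(denominator),
                 percent = percent_of(counts, denominator))
}

#' Demographic and outcome frequency table for a cohort
#'
#' Rows for age bands, reporter types, serious outcomes, country groups and
#' sex, plus weight median and quartiles. Age/reporter/sex/country percents
#' use the cohort size as denominator; the serious-outcomes block uses the
#' total number of outcome codes (death and life-threatening are combined
#' into one display category).
#'
#' @param cohort a `faers_cohort` or `faers_cases`
#' @return tibble with columns `variable`, `level`, `count`, `denominator`,
#'   `percent`, `value` (numeric; used by the weight rows only)
#' @export
demographics_table <- function(cohort) {
  cas <- if (inherits(cohort, "faers_cohort")) cohort$cases else cohort
  n <- n_cases(cas)
  if (n == 0L) {
    return(tibble::tibble(variable = character(), level = character(),
                          count = integer(), denominator = integer(),
                          percent = numeric(), value = numeric()))
  }
  d <- cas$demo
  count_levels <- function(x, levels) {
    as.integer(table(factor(x, levels = levels)))
  }

  age_levels <- c("<20", "20-50", "50-65", ">=65", "unknown")
  reporter_levels <- c("physician", "consumer", "other_health_professional",
                       "pharmacist", "lawyer", "unknown")
  country_levels <- c("Europe", "United States", "Japan", "South America",
                      "other")
  sex_levels <- c("female", "male", "unknown")

  oc <- cas$outcomes$outcome
  oc_grouped <- ifelse(oc %in% c("death", "life_threatening"),
                       "life_threatening_death", oc)
  outcome_levels <- c("hospitalization", "other_serious",
                      "life_threatening_death", "disability",
                      "congenital_anomaly")
  oc_counts <- count_levels(oc_grouped, outcome_levels)
  oc_denom <- sum(oc_counts)

  wt <- d$weight_kg[!is.na(d$weight_kg)]
  wt_stats <- if (length(wt) > 0) {
    stats::quantile(wt, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  } else {
    rep(NA_real_, 3)
  }

  out <- dplyr::bind_rows(
    freq_block("age", age_levels, count_levels(d$age_band, age_levels), n),
    freq_block("reporter", reporter_levels,
               count_levels(d$reporter, reporter_levels), n),
    freq_block("outcome", outcome_levels, oc_counts, oc_denom),
    freq_block("country", country_levels,
               count_levels(d$country_group, country_levels), n),
    freq_block("sex", sex_levels, count_levels(d$sex, sex_levels), n)
  )
  out$value <- NA_real_
  weight_rows <- tibble::tibble(
    variable = "weight_kg", level = c("median", "q1", "q3"),
    count = NA_integer_, denominator = NA_integer_, percent = NA_real_,
    value = wt_stats)
  dplyr::bind_rows(out, weight_rows)
}

# number of analysis-view adverse events (distinct case x term) in a cohort
cohort_ae_total <- function(cohort) {
  ar <- dplyr::distinct(analysis_reactions(cohort)[, c("case_id", "pt")])
  nrow(ar)
}

#' Endpoint frequency table across cohorts
#'
#' Counting unit is endpoint hits (a case contributes once per endpoint).
#' Denominator conventions: the `Total` rows use the total number of
#' analysis-view adverse events (distinct case x term) across all cohorts;
#' per-drug rows use that drug's adverse-event total; per-sex rows use the
#' drug x sex adverse-event totals.
#'
#' @param cohorts named list of `faers_cohort` objects
#' @param endpoints endpoint dictionary
#' @return tibble with columns `drug` (`"Total"` or cohort label), `sex`
#'   (`"all"` or sex level), `endpoint`, `count`, `denominator`, `percent`
#' @export
endpoint_frequency_table <- function(cohorts, endpoints = load_endpoints()) {
  eps <- unique(endpoints$endpoint)
  per <- lapply(names(cohorts), function(lab) {
    co <- cohorts[[lab]]
    ar <- dplyr::distinct(analysis_reactions(co)[, c("case_id", "pt")])
    hits <- map_endpoints(ar, endpoints)
    sex <- co$cases$demo$sex[match(hits$case_id, co$cases$demo$case_id)]
    ae_sex <- table(factor(
      co$cases$demo$sex[match(ar$case_id, co$cases$demo$case_id)],
      levels = c("female", "male", "unknown")))
    list(label = lab, hits = hits, hit_sex = sex, ae_total = nrow(ar),
         ae_sex = ae_sex)
  })
  total_aes <- sum(vapply(per, `[[`, numeric(1), "ae_total"))

  rows <- list()
  for (e in eps) {
    tot <- sum(vapply(per, function(p) sum(p$hits$endpoint == e),
                      numeric(1)))
    rows[[paste("Total", e)]] <- tibble::tibble(
      drug = "Total", sex = "all", endpoint = e, count = as.integer(tot),
      denominator = as.integer(total_aes),
      percent = percent_of(tot, total_aes))
  }
  for (p in per) {
    for (e in eps) {
      sel <- p$hits$endpoint == e
      rows[[paste(p$label, e)]] <- tibble::tibble(
        drug = p$label, sex = "all", endpoint = e,
        count = as.integer(sum(sel)),
        denominator = as.integer(p$ae_total),
        percent = percent_of(sum(sel), p$ae_total))
      for (s in c("female", "male", "unknown")) {
        cnt <- sum(sel & p$hit_sex == s)
        den <- as.integer(p$ae_sex[[s]])
        rows[[paste(p$label, e, s)]] <- tibble::tibble(
          drug = p$label, sex = s, endpoint = e, count = as.integer(cnt),
          denominator = den, percent = percent_of(cnt, den))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Top concomitant anti-parkinsonian drugs in a cohort
#'
#' Counts cohort cases listing each dictionary drug among their drug
#' entries (any role; substring match on verbatim name and active
#' ingredient), excluding the cohort's own target patterns and levodopa.
#' Percent denominator is the cohort's total drug-entry count. Ties are
#' broken alphabetically.
#'
#' @param cohort a `faers_cohort` (its query supplies the target patterns)
#'   or `faers_cases`
#' @param anti_pd_drugs dictionary of anti-parkinsonian drug names
#' @param k number of top entries to return (all if larger than the
#'   dictionary)
#' @param exclude_patterns extra patterns to exclude; defaults to
#'   `"levodopa"` plus the cohort query's target patterns when available
#' @return tibble `drug`, `count`, `denominator`, `percent`, sorted by
#'   descending count then name
#' @export
concomitant_ranking <- function(cohort, anti_pd_drugs = load_anti_pd_drugs(),
                                k = 5, exclude_patterns = NULL) {
  if (length(anti_pd_drugs) == 0L) {
    stop("concomitant_ranking: empty anti-parkinsonian drug dictionary",
         call. = FALSE)
  }
  cas <- if (inherits(cohort, "faers_cohort")) cohort$cases else cohort
  if (is.null(exclude_patterns)) exclude_patterns <- "levodopa"
  keep <- setdiff(anti_pd_drugs, tolower(exclude_patterns))
  dr <- cas$drugs
  denom <- nrow(dr)
  counts <- vapply(keep, function(g) {
    hit <- match_any_pattern(g, dr$name_raw, dr$active_ingredient)
    length(unique(dr$case_id[hit]))
  }, numeric(1))
  out <- tibble::tibble(drug = keep, count = as.integer(counts),
                        denominator = as.integer(denom),
                        percent = percent_of(counts, denom))
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(-out$count, out$drug), , drop = FALSE]
  utils::head(out, n = min(k, nrow(out)))
}

#' Two-sided 2x2 subgroup comparison
#'
#' Pearson chi-square without continuity correction when all expected cells
#' are at least 5, otherwise Fisher's exact test (two-sided). A table with
#' a zero margin is degenerate and returns p = 1.
#'
#' @param counts a 2x2 integer matrix, or a length-4 vector `(a, b, c, d)`
#'   read row-wise
#' @param correct apply Yates continuity correction to the chi-square
#'   branch (default FALSE)
#' @return list with `counts`, `method` (`"chi_square"` or `"fisher"`),
#'   `statistic` (chi-square only), `p_value`, `degenerate`
#' @export
subgroup_compare <- function(counts, correct = FALSE) {
  m <- if (is.matrix(counts)) counts else matrix(counts, 2, 2, byrow = TRUE)
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 0)) {
    stop("subgroup_compare: counts must be nonnegative integers",
         call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(counts = m, method = "degenerate", statistic = NA_real_,
                p_value = 1, degenerate = TRUE))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(m, alternative = "two.sided")
    list(counts = m, method = "fisher", statistic = NA_real_,
         p_value = ft$p.value, degenerate = FALSE)
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
    list(counts = m, method = "chi_square",
         statistic = unname(ct$statistic), p_value = ct$p.value,
         degenerate = FALSE)
  }
}

#' Female-vs-male endpoint comparisons within each cohort
#'
#' For each cohort x endpoint, compares the proportion of endpoint hits
#' among female vs male adverse-event totals with [subgroup_compare()].
#'
#' @param cohorts named list of `faers_cohort` objects
#' @param endpoints endpoint dictionary
#' @return tibble `drug`, `endpoint`, counts, `method`, `p_value`, `stars`
#' @export
endpoint_sex_tests <- function(cohorts, endpoints = load_endpoints()) {
  freq <- endpoint_frequency_table(cohorts, endpoints)
  rows <- list()
  for (lab in names(cohorts)) {
    for (e in unique(endpoints$endpoint)) {
      fr <- freq[freq$drug == lab & freq$endpoint == e, , drop = FALSE]
      f <- fr[fr$sex == "female", ]; m <- fr[fr$sex == "male", ]
      tst <- subgroup_compare(c(f$count, f$denominator - f$count,
                                m$count, m$denominator - m$count))
      rows[[paste(lab, e)]] <- tibble::tibble(
        drug = lab, endpoint = e,
        female_hits = f$count, female_aes = f$denominator,
        male_hits = m$count, male_aes = m$denominator,
        method = tst$method, p_value = tst$p_value,
        stars = significance_stars(tst$p_value))
    }
  }
  dplyr::bind_rows(rows)
}

#' Significance stars in the study's convention
#'
#' `*` for p < 0.05, `***` for p < 0.001, empty otherwise.
#'
#' @param p numeric vector of p values
#' @return character vector
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.05, "*", "")))
}

#' Adverse event report counts per calendar quarter
#'
#' @param cohort a `faers_cohort` or `faers_cases`
#' @return tibble `quarter` (e.g. `"2018Q3"`), `count`; reports with no
#'   parseable received date are grouped under `"unknown"`
#' @export
quarter_counts <- function(cohort) {
  cas <- if (inherits(cohort, "faers_cohort")) cohort$cases else cohort
  d <- cas$demo$received_date
  q <- ifelse(is.na(d), "unknown",
              paste0(format(d, "%Y"), "Q",
                     (as.integer(format(d, "%m")) - 1L) %/% 3L + 1L))
  tab <- table(q)
  tibble::tibble(quarter = names(tab), count = as.integer(tab))
}
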