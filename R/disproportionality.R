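# Disproportionality statistics on the report-level 2x2 table
#
#               endpoint   no endpoint
#   target drug     a          b
#   comparator      c          d
#
# ROR with Wald intervals, the BCPNN information component in its modern
# shrinkage form, and the MGPS empirical Bayes geometric mean under a
# two-component gamma mixture prior (see R/mgps.R), combined into the
# joint signal criterion ROR >= 3 & CI low > 1, IC025 > 0, EB05 > 2.

#' Construct a 2x2 contingency table
#'
#' @param a reports with target drug and endpoint
#' @param b reports with target drug, without endpoint
#' @param c reports with endpoint, without target drug
#' @param d reports with neither
#' @return a `contingency_table` object
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("contingency_table: cells must be nonnegative integers",
         call. = FALSE)
  }
  if (sum(cells) == 0) {
    stop("contingency_table: empty table (N = 0)", call. = FALSE)
  }
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2> a=%d b=%d c=%d d=%d (N=%d)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Build the drug-endpoint 2x2 table from a cohort and a comparator
#'
#' Counting is report-level: a case counts once per endpoint however many
#' member terms it lists. The cohort is counted on its analysis view
#' (SOC-whitelisted reactions); the comparator on its full reaction table.
#'
#' @param cohort a `faers_cohort` (or `faers_cases`) — the exposed set
#' @param background a `faers_cases` comparator, disjoint from the cohort
#' @param endpoint endpoint name to count
#' @param endpoints endpoint dictionary
#' @return a `contingency_table`
#' @export
build_table <- function(cohort, background, endpoint,
                        endpoints = load_endpoints()) {
  coh_cases <- if (inherits(cohort, "faers_cohort")) cohort$cases else cohort
  n1 <- n_cases(coh_cases)
  n0 <- n_cases(background)
  if (n1 + n0 == 0L) stop("build_table: no cases (N = 0)", call. = FALSE)
  overlap <- intersect(coh_cases$demo$case_id, background$demo$case_id)
  if (length(overlap) > 0L) {
    stop("build_table: cohort and comparator share ", length(overlap),
         " case(s); they must be disjoint", call. = FALSE)
  }
  a <- endpoint_counts(analysis_reactions(cohort), endpoints)[[endpoint]]
  c_ <- endpoint_counts(background$reactions, endpoints)[[endpoint]]
  contingency_table(a, n1 - a, c_, n0 - c_)
}

#' Reporting odds ratio with 95% Wald interval
#'
#' ROR = (a d)/(b c); the interval is exp(log ROR +/- 1.96 sqrt(1/a + 1/b +
#' 1/c + 1/d)). If any cell is zero, 0.5 is added to all four cells first
#' (Haldane-Anscombe) and the result is flagged `corrected`.
#'
#' @param t a [contingency_table()]
#' @return list with `ror`, `ci_low`, `ci_high`, `corrected`
#' @export
ror <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  structure(list(ror = est,
                 ci_low = exp(log(est) - 1.96 * se),
                 ci_high = exp(log(est) + 1.96 * se),
                 corrected = corrected),
            class = "ror_result")
}

#' BCPNN information component with lower credible bound
#'
#' The information component in its shrinkage form,
#' IC = log2((a + 0.5) / (E + 0.5)) with E = (a+b)(a+c)/N, and the
#' closed-form approximation to the lower 95% credible bound,
#' IC025 = IC - 3.3 (a + 0.5)^(-1/2) - 2.0 (a + 0.5)^(-3/2).
#'
#' @param t a [contingency_table()]
#' @return list with `ic`, `ic025`, `expected`
#' @export
bcpnn_ic <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  n <- t$a + t$b + t$c + t$d
  e <- (t$a + t$b) * (t$a + t$c) / n
  ic <- log2((t$a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (t$a + 0.5)^(-0.5) - 2.0 * (t$a + 0.5)^(-1.5)
  structure(list(ic = ic, ic025 = ic025, expected = e),
            class = "ic_result")
}

#' Apply the joint signal criterion
#'
#' A drug-event pair is a signal when all three rules hold: ROR >= 3 with
#' Wald CI lower bound > 1; IC lower credible bound > 0; EBGM 5th posterior
#' percentile > 2.
#'
#' @param ror_r a [ror()] result
#' @param ic_r a [bcpnn_ic()] result
#' @param ebgm_r an [ebgm()] result
#' @return list with `is_signal` and `criteria_met` (named logical vector
#'   `ror_rule`, `ic_rule`, `ebgm_rule`)
#' @export
evaluate_signal <- function(ror_r, ic_r, ebgm_r) {
  rules <- c(ror_rule = isTRUE(ror_r$ror >= 3 && ror_r$ci_low > 1),
             ic_rule = isTRUE(ic_r$ic025 > 0),
             ebgm_rule = isTRUE(ebgm_r$eb05 > 2))
  list(is_signal = all(rules), criteria_met = rules)
}

#' Disproportionality results for all cohort x endpoint pairs
#'
#' Builds the 2x2 tables for every cohort against its comparator, computes
#' ROR, IC and EBGM (under one MGPS prior fitted across all supplied
#' drug-term pairs), and applies the joint signal criterion.
#'
#' @param cohorts named list of `faers_cohort` objects
#' @param all_cases the full deduplicated case set the cohorts were drawn
#'   from (the comparator for a cohort is `all_cases` minus that cohort
#'   when `comparator = "all"`, or the union of the screened cohorts minus
#'   that cohort when `comparator = "screened"`)
#' @param endpoints endpoint dictionary
#' @param comparator comparator population, see above
#' @param prior_pairs `"all_pts"` fits the MGPS prior over every drug x
#'   observed-reaction-term table (recommended: many pairs identify the
#'   five hyperparameters); `"endpoints"` uses only the cohort x endpoint
#'   tables
#' @param prior optionally a pre-fitted [fit_mgps_prior()] result
#' @return tibble with one row per cohort x endpoint: counts, all three
#'   statistics with bounds, and the signal decision; the fitted prior is
#'   attached as attribute `prior`
#' @export
disproportionality_table <- function(cohorts, all_cases,
                                     endpoints = load_endpoints(),
                                     comparator = c("all", "screened"),
                                     prior_pairs = c("all_pts", "endpoints"),
                                     prior = NULL) {
  comparator <- match.arg(comparator)
  prior_pairs <- match.arg(prior_pairs)
  screened_ids <- unique(unlist(lapply(cohorts,
                                       function(co) co$cases$demo$case_id)))
  rows <- list()
  for (lab in names(cohorts)) {
    co <- cohorts[[lab]]
    coh_ids <- co$cases$demo$case_id
    bg_ids <- if (comparator == "all") {
      setdiff(all_cases$demo$case_id, coh_ids)
    } else {
      setdiff(screened_ids, coh_ids)
    }
    background <- subset_cases(all_cases, bg_ids)
    for (e in unique(endpoints$endpoint)) {
      t <- build_table(co, background, e, endpoints)
      rows[[paste(lab, e)]] <- tibble::tibble(
        drug = lab, endpoint = e, a = t$a, b = t$b, c = t$c, d = t$d)
    }
  }
  res <- dplyr::bind_rows(rows)

  if (is.null(prior)) {
    prior_tabs <- if (prior_pairs == "all_pts") {
      drug_pt_tables(cohorts, all_cases, comparator)
    } else {
      data.frame(a = res$a,
                 E = (res$a + res$b) * (res$a + res$c) /
                   (res$a + res$b + res$c + res$d))
    }
    prior <- fit_mgps_prior(prior_tabs)
  }

  stat_rows <- lapply(seq_len(nrow(res)), function(i) {
    t <- contingency_table(res$a[i], res$b[i], res$c[i], res$d[i])
    r <- ror(t); ic <- bcpnn_ic(t)
    if (ic$expected > 0) {
      eb <- ebgm(t, prior)
    } else {
      # endpoint absent from cohort and comparator alike: the posterior of
      # the reporting-rate ratio is undefined; no signal by definition
      eb <- list(ebgm = NA_real_, eb05 = NA_real_, eb95 = NA_real_,
                 posterior_weight = NA_real_)
    }
    sg <- evaluate_signal(r, ic, eb)
    tibble::tibble(ROR = r$ror, ROR_low = r$ci_low, ROR_high = r$ci_high,
                   ROR_corrected = r$corrected,
                   IC = ic$ic, IC025 = ic$ic025,
                   EBGM = eb$ebgm, EB05 = eb$eb05, EB95 = eb$eb95,
                   signal = sg$is_signal)
  })
  out <- dplyr::bind_cols(res, dplyr::bind_rows(stat_rows))
  attr(out, "prior") <- prior
  attr(out, "n_tests") <- nrow(out)
  out
}

# observed (a, E) pairs for every cohort drug x reaction term, used to fit
# the MGPS prior across the whole run
drug_pt_tables <- function(cohorts, all_cases, comparator = "all") {
  screened_ids <- unique(unlist(lapply(cohorts,
                                       function(co) co$cases$demo$case_id)))
  all_pts <- unique(all_cases$reactions$pt)
  out <- list()
  for (lab in names(cohorts)) {
    co <- cohorts[[lab]]
    coh_ids <- unique(co$cases$demo$case_id)
    bg_ids <- if (comparator == "all") {
      setdiff(all_cases$demo$case_id, coh_ids)
    } else {
      setdiff(screened_ids, coh_ids)
    }
    n1 <- length(coh_ids); n0 <- length(bg_ids)
    reac <- dplyr::distinct(all_cases$reactions)
    in_coh <- reac$case_id %in% coh_ids
    a_tab <- table(factor(reac$pt[in_coh], levels = all_pts))
    c_tab <- table(factor(reac$pt[reac$case_id %in% bg_ids],
                          levels = all_pts))
    a <- as.integer(a_tab); cc <- as.integer(c_tab)
    n <- n1 + n0
    e <- (a + (n1 - a)) * (a + cc) / n  # = n1 * (a + c) / N
    out[[lab]] <- data.frame(drug = lab, pt = all_pts, a = a, E = e)
  }
  d <- dplyr::bind_rows(out)
  d[d$E > 0, , drop = FALSE]
}

#' Format a disproportionality table for display
#'
#' Two-decimal display variant (half-up rounding) in the conventional
#' `estimate (low, high)` style.
#'
#' @param tab output of [disproportionality_table()]
#' @return tibble with display columns
#' @export
format_signal_table <- function(tab) {
  f <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)
  tibble::tibble(
    drug = tab$drug, endpoint = tab$endpoint, N = tab$a,
    `ROR (95% CI)` = sprintf("%s (%s, %s)", f(tab$ROR), f(tab$ROR_low),
                             f(tab$ROR_high)),
    `IC (IC025)` = sprintf("%s (%s)", f(tab$IC), f(tab$IC025)),
    `EBGM (EBGM05)` = sprintf("%s (%s)", f(tab$EBGM), f(tab$EB05)),
    signal = ifelse(tab$signal, "yes", "no")
  )
}
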