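# Published summary counts for the benserazide (BSZ) vs carbidopa (CD)
# motor-complication cohorts, bundled as plain-text inputs. They let the
# descriptive percent conventions and the joint signal criterion be
# validated on fully printed numbers without the multi-gigabyte FAERS
# download.

ref_path <- function(name) {
  p <- system.file("extdata", "reference", name, package = "faersignal")
  if (p == "") stop("bundled reference table not found: ", name,
                    call. = FALSE)
  p
}

#' Bundled reference summary tables
#'
#' `load_reference_demographics()`: per-cohort demographic and outcome
#' counts. `load_reference_cohort_sizes()`: the two cohort report totals.
#' `load_reference_endpoint_counts()`: motor-complication report counts per
#' endpoint. `load_reference_ae_total()`: the combined adverse-event total
#' across both cohorts. `load_reference_signal_measures()`: the published
#' (ROR, CI, IC025, EBGM05) tuples per drug x endpoint.
#'
#' @return a tibble (or scalar for the AE total)
#' @name reference-tables
NULL

#' @rdname reference-tables
#' @export
load_reference_demographics <- function() {
  tibble::as_tibble(read_dict(ref_path("cohort_demographics.tsv")))
}

#' @rdname reference-tables
#' @export
load_reference_cohort_sizes <- function() {
  tibble::as_tibble(read_dict(ref_path("cohort_sizes.tsv")))
}

#' @rdname reference-tables
#' @export
load_reference_endpoint_counts <- function() {
  tibble::as_tibble(read_dict(ref_path("motor_complication_counts.tsv")))
}

#' @rdname reference-tables
#' @export
load_reference_ae_total <- function() {
  read_dict(ref_path("ae_totals.tsv"))$n_aes[[1]]
}

#' @rdname reference-tables
#' @export
load_reference_signal_measures <- function() {
  tibble::as_tibble(read_dict(ref_path("signal_measures.tsv")))
}

#' Percent columns for the reference demographic counts
#'
#' Applies the study's denominator conventions to the bundled counts:
#' cohort size for age/reporter/sex/country blocks, the summed
#' outcome-category count for the serious-outcomes block.
#'
#' @return tibble `drug`, `variable`, `level`, `count`, `denominator`,
#'   `percent`
#' @export
reference_demographic_percents <- function() {
  d <- load_reference_demographics()
  sizes <- load_reference_cohort_sizes()
  d$denominator <- NA_integer_
  for (g in unique(d$drug)) {
    sel <- d$drug == g
    n_rep <- sizes$n_reports[sizes$drug == g]
    out_sel <- sel & d$variable == "outcome"
    d$denominator[sel] <- n_rep
    d$denominator[out_sel] <- sum(d$count[out_sel])
  }
  d$percent <- percent_of(d$count, d$denominator)
  tibble::as_tibble(d)
}

#' Percent columns for the reference endpoint counts
#'
#' Total-row percents over the combined adverse-event total.
#'
#' @return tibble `endpoint`, `count`, `denominator`, `percent`
#' @export
reference_endpoint_percents <- function() {
  d <- load_reference_endpoint_counts()
  tot <- load_reference_ae_total()
  tibble::tibble(endpoint = d$endpoint, count = d$count_total,
                 denominator = as.integer(tot),
                 percent = percent_of(d$count_total, tot))
}

#' Joint signal criterion applied to the reference measure tuples
#'
#' Classifies every published (ROR, CI low, IC025, EBGM05) tuple with
#' [evaluate_signal()].
#'
#' @return tibble with `drug`, `endpoint`, the three rule columns and
#'   `is_signal`
#' @export
classify_reference_signals <- function() {
  d <- load_reference_signal_measures()
  rows <- lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    sg <- evaluate_signal(
      list(ror = r$ror, ci_low = r$ror_low, ci_high = r$ror_high),
      list(ic = r$ic, ic025 = r$ic025),
      list(ebgm = r$ebgm, eb05 = r$ebgm05))
    tibble::tibble(drug = r$drug, endpoint = r$endpoint,
                   ror_rule = sg$criteria_met[["ror_rule"]],
                   ic_rule = sg$criteria_met[["ic_rule"]],
                   ebgm_rule = sg$criteria_met[["ebgm_rule"]],
                   is_signal = sg$is_signal)
  })
  dplyr::bind_rows(rows)
}
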