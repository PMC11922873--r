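# Assembly of the analysis outputs: cross-drug comparisons, forest-plot
# data and figure, and the end-to-end pipeline driver.

#' Compare one endpoint's signal between two drugs
#'
#' Reports (i) whether the two RORs' 95% confidence intervals overlap
#' (non-overlap read as a significant difference) and (ii) the two-sided p
#' value from [subgroup_compare()] on the 2x2 of endpoint hits vs non-hits
#' across the two cohorts. Both are informative; neither is privileged.
#'
#' @param r1,r2 lists with elements `ror` (a [ror()] result) and `table`
#'   (the [contingency_table()] it was computed on), one per drug
#' @return list with `overlap` (logical), `p_value`, `method`
#' @export
compare_drugs <- function(r1, r2) {
  overlap <- r1$ror$ci_low <= r2$ror$ci_high &
    r2$ror$ci_low <= r1$ror$ci_high
  tst <- subgroup_compare(c(r1$table$a, r1$table$b, r2$table$a, r2$table$b))
  list(overlap = overlap, p_value = tst$p_value, method = tst$method)
}

#' Forest-plot data from a disproportionality table
#'
#' One row per drug x endpoint with the ROR and its interval, plus the
#' cross-drug comparison for each endpoint: CI overlap and the 2x2 test p
#' value; `significant_vs_other` is the p < 0.05 decision.
#'
#' @param tab output of [disproportionality_table()] (two drugs expected
#'   for the comparison columns; more are allowed, compared pairwise
#'   against the first other drug)
#' @return tibble `drug`, `endpoint`, `point`, `low`, `high`,
#'   `ci_overlap`, `p_vs_other`, `significant_vs_other`
#' @export
forest_data <- function(tab) {
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    this <- tab[i, ]
    other <- tab[tab$endpoint == this$endpoint & tab$drug != this$drug, ]
    if (nrow(other) >= 1L) {
      o <- other[1L, ]
      cmp <- compare_drugs(
        list(ror = list(ror = this$ROR, ci_low = this$ROR_low,
                        ci_high = this$ROR_high),
             table = contingency_table(this$a, this$b, this$c, this$d)),
        list(ror = list(ror = o$ROR, ci_low = o$ROR_low,
                        ci_high = o$ROR_high),
             table = contingency_table(o$a, o$b, o$c, o$d)))
      tibble::tibble(drug = this$drug, endpoint = this$endpoint,
                     point = this$ROR, low = this$ROR_low,
                     high = this$ROR_high, ci_overlap = cmp$overlap,
                     p_vs_other = cmp$p_value,
                     significant_vs_other = cmp$p_value < 0.05)
    } else {
      tibble::tibble(drug = this$drug, endpoint = this$endpoint,
                     point = this$ROR, low = this$ROR_low,
                     high = this$ROR_high, ci_overlap = NA,
                     p_vs_other = NA_real_, significant_vs_other = NA)
    }
  })
  dplyr::bind_rows(rows)
}

#' Forest plot of reporting odds ratios
#'
#' @param fd output of [forest_data()]
#' @return a ggplot object (log-scaled x axis, dashed unity line)
#' @export
plot_forest <- function(fd) {
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$point, y = .data$endpoint,
                                   colour = .data$drug)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$low,
                                         xmax = .data$high),
                            height = 0.2,
                            position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  colour = "Drug") +
    ggplot2::theme_minimal()
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Reads (or generates) the input data, deduplicates, screens the two
#' cohorts, and writes: the screening trace, the demographic and
#' concomitant-drug and endpoint-frequency tables, the disproportionality
#' signal table (full precision and 2-decimal display), forest data (and
#' figure), per-quarter report counts and a run manifest. Rerunning with
#' the same inputs and configuration reproduces the tables exactly.
#'
#' @param input either a directory containing one FAERS-dialect quarter, a
#'   `faers_raw` object, or a [synthetic_config()] (generated with `seed`)
#' @param out_dir artifact directory, created if missing
#' @param seed integer seed (used when `input` is a synthetic
#'   configuration; recorded in the manifest regardless)
#' @param config a [screening_config()]
#' @param endpoints endpoint dictionary
#' @param comparator comparator population passed to
#'   [disproportionality_table()]
#' @param make_figure write `forest.pdf` (default TRUE)
#' @return invisibly, a list with the in-memory results (`cases`,
#'   `cohorts`, `trace`, `signal_table`, `forest`, manifest path)
#' @export
run_pipeline <- function(input, out_dir, seed = 1,
                         config = screening_config(),
                         endpoints = load_endpoints(),
                         comparator = c("all", "screened"),
                         make_figure = TRUE) {
  comparator <- match.arg(comparator)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (inherits(input, "synthetic_config")) {
    raw <- generate_synthetic_faers(input, seed = seed)$raw
  } else if (inherits(input, "faers_raw")) {
    raw <- input
  } else if (is.character(input) && dir.exists(input)) {
    raw <- read_quarter(faers_quarter_paths(input))
  } else {
    stop("run_pipeline: input must be a synthetic_config, a faers_raw, ",
         "or a directory of FAERS-dialect files", call. = FALSE)
  }

  cases <- deduplicate(raw)
  scr <- run_cascade(cases, config)

  write_tsv <- function(d, name) {
    utils::write.table(as.data.frame(d), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }

  write_tsv(scr$trace, "screening_trace.tsv")
  for (lab in names(scr$cohorts)) {
    write_tsv(scr$cohorts[[lab]]$trace,
              sprintf("screening_trace_%s.tsv", lab))
    write_tsv(demographics_table(scr$cohorts[[lab]]),
              sprintf("table_demographics_%s.tsv", lab))
    write_tsv(concomitant_ranking(scr$cohorts[[lab]]),
              sprintf("table_concomitant_%s.tsv", lab))
    write_tsv(quarter_counts(scr$cohorts[[lab]]),
              sprintf("quarter_counts_%s.tsv", lab))
  }
  write_tsv(endpoint_frequency_table(scr$cohorts, endpoints),
            "table_endpoints.tsv")
  write_tsv(endpoint_sex_tests(scr$cohorts, endpoints),
            "table_endpoint_sex_tests.tsv")

  sig <- disproportionality_table(scr$cohorts, cases, endpoints,
                                  comparator = comparator)
  write_tsv(sig, "signal_table.tsv")
  write_tsv(format_signal_table(sig), "signal_table_display.tsv")
  fd <- forest_data(sig)
  write_tsv(fd, "forest_data.tsv")
  if (make_figure) {
    p <- plot_forest(fd)
    ggplot2::ggsave(file.path(out_dir, "forest.pdf"), p, width = 7,
                    height = 4)
  }

  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(
    comparator = comparator,
    queries = lapply(config$queries, unclass),
    soc_whitelist = config$soc_whitelist,
    stages = as.list(config$stages),
    drop_dual = config$drop_dual), cfg_json, auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  manifest <- list(
    seed = seed,
    n_cases = n_cases(cases),
    cohort_sizes = lapply(scr$cohorts, function(co) n_cases(co$cases)),
    n_tests = attr(sig, "n_tests"),
    config_md5 = unname(tools::md5sum(cfg_json)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("faersignal")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cases = cases, cohorts = scr$cohorts, trace = scr$trace,
                 signal_table = sig, forest = fd,
                 manifest = file.path(out_dir, "manifest.json")))
}
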