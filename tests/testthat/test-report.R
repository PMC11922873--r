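test_that("CI overlap comparison matches the published interval pairs", {
  mk <- function(ror, lo, hi, a, b, c, d) {
    list(ror = list(ror = ror, ci_low = lo, ci_high = hi),
         table = contingency_table(a, b, c, d))
  }
  # dyskinesia: (14.76, 18.45) vs (13.02, 14.65) do not overlap
  cmp <- compare_drugs(mk(16.5, 14.76, 18.45, 342, 1113, 1214, 6075),
                       mk(13.81, 13.02, 14.65, 1214, 6075, 342, 1113))
  expect_false(cmp$overlap)
  # on-off: (145.03, 201.01) vs (59.46, 76.63) do not overlap
  cmp2 <- compare_drugs(mk(170.74, 145.03, 201.01, 157, 1298, 261, 7028),
                        mk(67.5, 59.46, 76.63, 261, 7028, 157, 1298))
  expect_false(cmp2$overlap)
  # identical intervals and identical tables: overlap, p ~ 1
  r <- mk(2, 1.5, 2.7, 30, 70, 30, 70)
  cmp3 <- compare_drugs(r, r)
  expect_true(cmp3$overlap)
  expect_equal(cmp3$p_value, 1, tolerance = 1e-9)
})

test_that("run_pipeline emits every artifact and is reproducible", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- synthetic_config(n_cases = 1200)
  res <- suppressMessages(suppressWarnings(
    run_pipeline(cfg, out1, seed = 7, make_figure = TRUE)))
  files <- c("screening_trace.tsv", "screening_trace_BSZ.tsv",
             "table_demographics_BSZ.tsv", "table_demographics_CD.tsv",
             "table_concomitant_BSZ.tsv", "table_endpoints.tsv",
             "table_endpoint_sex_tests.tsv", "signal_table.tsv",
             "signal_table_display.tsv", "forest_data.tsv",
             "quarter_counts_BSZ.tsv", "forest.pdf", "manifest.json",
             "config.json")
  for (f in files) expect_true(file.exists(file.path(out1, f)), label = f)
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$seed, 7L)
  expect_equal(manifest$n_cases, 1200L)
  # determinism: identical inputs give identical result tables
  suppressMessages(suppressWarnings(
    run_pipeline(cfg, out2, seed = 7, make_figure = FALSE)))
  for (f in setdiff(files, c("forest.pdf", "manifest.json", "config.json"))) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  }
  expect_s3_class(res$signal_table, "data.frame")
  expect_true(all(c("ROR", "IC025", "EB05", "signal") %in%
                    names(res$signal_table)))
})

test_that("display tables round half-up to two decimals", {
  expect_equal(round_half_up(2.145), 2.15)
  expect_equal(round_half_up(2.144), 2.14)
  expect_equal(round_half_up(-2.145), -2.15)
  tab <- tibble::tibble(drug = "X", endpoint = "e", a = 3, b = 7, c = 9,
                        d = 81, ROR = 3.8571428, ROR_low = 1.00490,
                        ROR_high = 14.80551, ROR_corrected = FALSE,
                        IC = 1.234567, IC025 = 0.005, EBGM = 2.71828,
                        EB05 = 1.995, EB95 = 5.4321, signal = FALSE)
  disp <- format_signal_table(tab)
  expect_equal(disp$`ROR (95% CI)`, "3.86 (1.00, 14.81)")
  expect_equal(disp$`IC (IC025)`, "1.23 (0.01)")
  expect_equal(disp$`EBGM (EBGM05)`, "2.72 (2.00)")
})

test_that("forest data carries the cross-drug comparison per endpoint", {
  tab <- tibble::tibble(
    drug = c("A", "B"), endpoint = c("e1", "e1"),
    a = c(50, 10), b = c(50, 90), c = c(10, 50), d = c(90, 50),
    ROR = c(9, 0.11), ROR_low = c(4, 0.05), ROR_high = c(20, 0.24),
    ROR_corrected = FALSE, IC = 1, IC025 = 0.5, EBGM = 5, EB05 = 2.5,
    EB95 = 9, signal = TRUE)
  fd <- forest_data(tab)
  expect_equal(nrow(fd), 2L)
  expect_false(fd$ci_overlap[1])
  expect_true(all(fd$significant_vs_other))
  expect_true(all(fd$low <= fd$point & fd$point <= fd$high))
  p <- plot_forest(fd)
  expect_s3_class(p, "ggplot")
})
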