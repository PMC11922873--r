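bsz_query <- function() default_drug_queries()$BSZ

test_that("combination products satisfy both target and partner patterns", {
  raw <- bind_raw(list(eligible_case("1")))
  cases <- deduplicate(raw)
  hit <- select_drug_reports(cases, bsz_query())
  expect_equal(n_cases(hit), 1L)
  # a carbidopa-only case is excluded from the benserazide cohort
  raw2 <- make_raw(
    demo = demo_row("21", "2"),
    drug = drug_row("21", "2", drugname = "SINEMET",
                    prod_ai = "LEVODOPA\\CARBIDOPA"),
    reac = reac_row("21", "2", "Dyskinesia"))
  expect_equal(n_cases(select_drug_reports(deduplicate(raw2), bsz_query())),
               0L)
  # suspect-role requirement: concomitant-only mention does not match
  raw3 <- make_raw(
    demo = demo_row("31", "3"),
    drug = drug_row("31", "3", role_cod = "C"),
    reac = reac_row("31", "3", "Dyskinesia"))
  expect_equal(n_cases(select_drug_reports(deduplicate(raw3), bsz_query())),
               0L)
})

test_that("oral-route filter applies to the matched entries only", {
  mk <- function(route) {
    raw <- make_raw(
      demo = demo_row("11", "1"),
      drug = dplyr::bind_rows(
        drug_row("11", "1", drug_seq = "1", route = route),
        # an unrelated non-oral concomitant drug must not exclude the case
        drug_row("11", "1", drug_seq = "2", role_cod = "C",
                 drugname = "ROTIGOTINE", prod_ai = "ROTIGOTINE",
                 route = "TRANSDERMAL")),
      reac = reac_row("11", "1", "Dyskinesia"))
    filter_oral_route(select_drug_reports(deduplicate(raw), bsz_query()))
  }
  expect_equal(n_cases(mk("ORAL")), 1L)
  expect_equal(n_cases(mk("INTESTINAL INFUSION")), 0L)
  expect_equal(n_cases(mk("")), 0L)  # unknown route excluded
})

test_that("indication filter enforces PD indication and exclusion families", {
  mk <- function(reacs, indi_pt = "Parkinson's disease") {
    pid <- "11"
    raw <- make_raw(
      demo = demo_row(pid, "1"),
      drug = drug_row(pid, "1"),
      reac = dplyr::bind_rows(lapply(reacs, reac_row, primaryid = pid,
                                     caseid = "1")),
      indi = if (is.null(indi_pt)) NULL else indi_row(pid, "1",
                                                      indi_pt = indi_pt))
    filter_indication(select_drug_reports(deduplicate(raw), bsz_query()))
  }
  expect_equal(n_cases(mk("Dyskinesia")), 1L)
  expect_equal(n_cases(mk("Dyskinesia", indi_pt = NULL)), 0L)
  expect_equal(n_cases(mk("Dyskinesia", indi_pt = "Restless legs syndrome")),
               0L)
  # PD reported as an adverse event excludes the case
  expect_equal(n_cases(mk(c("Dyskinesia", "Parkinson's disease"))), 0L)
  # dementia / psychosis family excludes the case
  expect_equal(n_cases(mk(c("Dyskinesia", "Dementia"))), 0L)
  expect_equal(n_cases(mk(c("Dyskinesia", "Psychotic disorder"))), 0L)
})

test_that("SOC filter keeps whitelisted reactions and masks the rest", {
  raw <- make_raw(
    demo = dplyr::bind_rows(demo_row("11", "1"), demo_row("21", "2")),
    drug = dplyr::bind_rows(drug_row("11", "1"), drug_row("21", "2")),
    reac = dplyr::bind_rows(
      reac_row("11", "1", "Dyskinesia"), reac_row("11", "1", "Nausea"),
      reac_row("21", "2", "Nausea")))
  cases <- deduplicate(raw)
  kept <- filter_soc(cases)
  expect_equal(kept$demo$case_id, "1")  # GI-only case 2 excluded
  ar <- analysis_reactions(kept)
  expect_equal(ar$pt, "Dyskinesia")  # non-motor SOC masked from analysis
  expect_setequal(kept$reactions$pt[kept$reactions$case_id == "1"],
                  c("Dyskinesia", "Nausea"))  # original list preserved
})

test_that("cascade trace matches planted stage targets exactly", {
  targets <- c(400, 250, 120, 60)
  cfg <- plant_flowchart(synthetic_config(n_cases = 1000,
                                          duplicate_fraction = 0.1),
                         targets)
  g <- suppressMessages(generate_synthetic_faers(cfg, seed = 21))
  cases <- suppressMessages(deduplicate(g$raw))
  scr <- suppressMessages(run_cascade(cases))
  tr <- scr$cohorts$BSZ$trace
  expect_equal(tr$count, c(1000L, targets))
  expect_equal(unname(g$truth$stage_counts), c(1000L, targets))
  # infeasible targets are rejected
  expect_error(plant_flowchart(synthetic_config(100), c(50, 60, 30, 10)),
               "non-increasing")
  expect_error(plant_flowchart(synthetic_config(100), c(200, 60, 30, 10)),
               "exceeds")
})

test_that("trace counts are non-increasing and filters are order-invariant", {
  g <- suppressMessages(generate_synthetic_faers(
    synthetic_config(n_cases = 800), seed = 33))
  cases <- suppressMessages(deduplicate(g$raw))
  scr <- suppressMessages(run_cascade(cases))
  for (co in scr$cohorts) expect_true(all(diff(co$trace$count) <= 0))
  expect_true(all(diff(scr$trace$count) <= 0))
  # permuting the filter stages preserves the terminal cohort
  q <- bsz_query()
  a <- suppressMessages(
    filter_soc(filter_indication(filter_oral_route(
      select_drug_reports(cases, q)))))
  b <- suppressMessages(
    filter_oral_route(filter_soc(filter_indication(
      select_drug_reports(cases, q)))))
  expect_setequal(a$demo$case_id, b$demo$case_id)
  expect_setequal(a$demo$case_id, scr$cohorts$BSZ$cases$demo$case_id)
})

test_that("terminal cohorts equal the generator's eligible sets", {
  for (seed in c(8, 81)) {
    g <- suppressMessages(generate_synthetic_faers(
      synthetic_config(n_cases = 600), seed = seed))
    cases <- suppressMessages(deduplicate(g$raw))
    scr <- suppressMessages(run_cascade(cases))
    el <- g$truth$eligibility
    expect_setequal(scr$cohorts$BSZ$cases$demo$case_id,
                    el$caseid[el$BSZ_eligible])
    expect_setequal(scr$cohorts$CD$cases$demo$case_id,
                    el$caseid[el$CD_eligible])
  }
})

test_that("empty input and disabled stages behave as documented", {
  g <- suppressMessages(generate_synthetic_faers(
    synthetic_config(n_cases = 200), seed = 2))
  cases <- suppressMessages(deduplicate(g$raw))
  # all post-match filters disabled: terminal count equals the drug match
  scr <- suppressMessages(run_cascade(cases, screening_config(
    stages = c(oral_route = FALSE, pd_indication = FALSE, soc = FALSE))))
  tr <- scr$cohorts$BSZ$trace
  expect_equal(tr$stage, c("input", "drug_match"))
  expect_equal(n_cases(scr$cohorts$BSZ$cases),
               tr$count[tr$stage == "drug_match"])
  # empty input: every stage count is zero
  empty <- subset_cases(cases, character(0))
  scr0 <- suppressMessages(run_cascade(empty))
  expect_true(all(scr0$trace$count == 0L))
})

test_that("dual-matching cases are flagged and can be dropped", {
  pid <- "11"
  raw <- make_raw(
    demo = demo_row(pid, "1"),
    drug = dplyr::bind_rows(
      drug_row(pid, "1", drug_seq = "1"),
      drug_row(pid, "1", drug_seq = "2", drugname = "SINEMET",
               prod_ai = "LEVODOPA\\CARBIDOPA")),
    reac = reac_row(pid, "1", "Dyskinesia"),
    indi = indi_row(pid, "1"))
  cases <- deduplicate(raw)
  scr <- run_cascade(cases)
  expect_true(scr$cohorts$BSZ$dual)
  expect_true(scr$cohorts$CD$dual)
  scr2 <- run_cascade(cases, screening_config(drop_dual = TRUE))
  expect_equal(n_cases(scr2$cohorts$BSZ$cases), 0L)
  expect_equal(n_cases(scr2$cohorts$CD$cases), 0L)
})
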