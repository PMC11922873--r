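test_that("demographic percents follow the block denominator conventions", {
  cases <- lapply(1:8, function(i) {
    ec <- eligible_case(as.character(i), sex = if (i <= 5) "F" else "M")
    ec$demo$age <- c("15", "30", "55", "70", "80", "72", "", "40")[i]
    ec$demo$age_cod <- ifelse(ec$demo$age == "", "", "YR")
    ec
  })
  raw <- bind_raw(cases)
  raw$outc <- dplyr::bind_rows(
    outc_row("11", "1", "HO"), outc_row("11", "1", "DE"),
    outc_row("21", "2", "HO"), outc_row("31", "3", "OT"))
  cases_dd <- deduplicate(raw)
  tab <- demographics_table(cases_dd)

  age <- tab[tab$variable == "age", ]
  expect_equal(age$denominator, rep(8L, 5))
  expect_equal(age$count[age$level == ">=65"], 3L)
  expect_equal(age$percent[age$level == ">=65"], 37.5)

  # outcomes: denominator is the number of outcome codes, not cases
  oc <- tab[tab$variable == "outcome", ]
  expect_equal(unique(oc$denominator), 4L)
  expect_equal(oc$count[oc$level == "hospitalization"], 2L)
  expect_equal(oc$percent[oc$level == "hospitalization"], 50)
  expect_equal(oc$count[oc$level == "life_threatening_death"], 1L)

  sex <- tab[tab$variable == "sex", ]
  expect_equal(sex$count[sex$level == "female"], 5L)
  expect_equal(sex$percent[sex$level == "female"],
               round_half_up(100 * 5 / 8))

  # every percent is re-derivable from (count, denominator)
  ok <- !is.na(tab$percent)
  expect_equal(tab$percent[ok],
               percent_of(tab$count[ok], tab$denominator[ok]))

  wt <- tab[tab$variable == "weight_kg", ]
  expect_equal(wt$value[wt$level == "median"], 70)
})

test_that("endpoint frequency denominators are AE totals at each level", {
  mk_cohort <- function(ids, pts_per_case, sexes) {
    cs <- Map(function(id, pts, sx) {
      pid <- paste0(id, "1")
      list(demo = demo_row(pid, id, sex = sx),
           drug = drug_row(pid, id),
           reac = dplyr::bind_rows(lapply(pts, reac_row, primaryid = pid,
                                          caseid = id)),
           indi = indi_row(pid, id))
    }, ids, pts_per_case, sexes)
    co_cases <- filter_soc(deduplicate(bind_raw(cs)))
    structure(list(label = "X", cases = co_cases,
                   trace = NULL, dual = FALSE), class = "faers_cohort")
  }
  # cohort A: 2 cases, AEs = 3 (Dyskinesia+Tremor, Tremor)
  a <- mk_cohort(c("1", "2"),
                 list(c("Dyskinesia", "Tremor"), "Tremor"), c("F", "M"))
  a$label <- "A"
  # cohort B: 1 case, AEs = 2 (Dystonia+Freezing phenomenon)
  b <- mk_cohort("3", list(c("Dystonia", "Freezing phenomenon")), "F")
  b$label <- "B"
  tab <- endpoint_frequency_table(list(A = a, B = b))
  tot <- tab[tab$drug == "Total" & tab$endpoint == "dyskinesia", ]
  expect_equal(tot$count, 2L)        # one hit per cohort
  expect_equal(tot$denominator, 5L)  # 3 + 2 AEs overall
  expect_equal(tot$percent, 40)
  pa <- tab[tab$drug == "A" & tab$sex == "all" &
              tab$endpoint == "dyskinesia", ]
  expect_equal(pa$denominator, 3L)
  pf <- tab[tab$drug == "A" & tab$sex == "female" &
              tab$endpoint == "dyskinesia", ]
  expect_equal(pf$count, 1L)
  expect_equal(pf$denominator, 2L)  # female case carries 2 AEs
})

test_that("concomitant ranking counts cases, breaks ties alphabetically", {
  cs <- lapply(1:6, function(i) {
    id <- as.character(i); pid <- paste0(id, "1")
    extra <- list(
      c("PRAMIPEXOLE", "AMANTADINE"), "PRAMIPEXOLE", "AMANTADINE",
      "RASAGILINE", "ROPINIROLE", "ROPINIROLE")[[i]]
    list(demo = demo_row(pid, id),
         drug = dplyr::bind_rows(
           drug_row(pid, id, drug_seq = "1"),
           dplyr::bind_rows(lapply(seq_along(extra), function(j) {
             drug_row(pid, id, drug_seq = as.character(j + 1),
                      role_cod = "C", drugname = extra[[j]],
                      prod_ai = extra[[j]])
           }))),
         reac = reac_row(pid, id, "Dyskinesia"),
         indi = indi_row(pid, id))
  })
  cases <- deduplicate(bind_raw(cs))
  rk <- concomitant_ranking(cases, k = 3)
  expect_equal(rk$drug, c("amantadine", "pramipexole", "ropinirole"))
  expect_equal(rk$count, c(2L, 2L, 2L))
  # denominator: total drug entries in the cohort (7 extras + 6 targets)
  expect_equal(unique(rk$denominator), 13L)
  # k beyond the dictionary returns everything observed
  expect_equal(nrow(concomitant_ranking(cases, k = 100)), 4L)
  expect_error(concomitant_ranking(cases, anti_pd_drugs = character(0)),
               "empty")
})

test_that("subgroup comparison picks its branch from expected cells", {
  # identical proportions: chi-square statistic 0, p = 1
  s0 <- subgroup_compare(c(10, 90, 10, 90))
  expect_equal(s0$method, "chi_square")
  expect_equal(s0$statistic, 0, tolerance = 1e-12)
  expect_equal(s0$p_value, 1, tolerance = 1e-12)
  # hand-computed Pearson statistic: expected (12.5, 87.5, 12.5, 87.5),
  # X2 = 2*(7.5^2/12.5) + 2*(7.5^2/87.5) = 72/7 = 10.2857
  s1 <- subgroup_compare(c(20, 80, 5, 95))
  expect_equal(s1$method, "chi_square")
  expect_equal(s1$statistic, 72 / 7, tolerance = 1e-9)
  expect_equal(s1$p_value, stats::pchisq(72 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # small expected cells trigger the exact test; note (1,9,9,2) has
  # min expected 10*10/21 = 4.76 < 5, while (1,9,9,1) sits exactly at 5
  # and stays on the chi-square branch
  s2 <- subgroup_compare(c(1, 9, 9, 2))
  expect_equal(s2$method, "fisher")
  expect_equal(s2$p_value, stats::fisher.test(matrix(c(1, 9, 9, 2), 2,
                                                     byrow = TRUE))$p.value)
  expect_equal(subgroup_compare(c(1, 9, 9, 1))$method, "chi_square")
  # zero margin: degenerate, p = 1
  s3 <- subgroup_compare(c(0, 0, 5, 7))
  expect_true(s3$degenerate)
  expect_equal(s3$p_value, 1)
})

test_that("subgroup comparison is invariant under row and column swaps", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(sample(0:60, 4, replace = TRUE), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    p <- subgroup_compare(m)$p_value
    expect_equal(subgroup_compare(m[2:1, ])$p_value, p, tolerance = 1e-9)
    expect_equal(subgroup_compare(m[, 2:1])$p_value, p, tolerance = 1e-9)
  }
})

test_that("significance stars follow the p-value convention", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.0005, NA)),
               c("", "*", "***", ""))
})

test_that("quarter counts group received dates by calendar quarter", {
  cs <- lapply(1:4, function(i) {
    ec <- eligible_case(as.character(i))
    ec$demo$event_dt <- c("20180115", "20180220", "20181001", "")[i]
    ec
  })
  qc <- quarter_counts(deduplicate(bind_raw(cs)))
  expect_equal(qc$count[qc$quarter == "2018Q1"], 2L)
  expect_equal(qc$count[qc$quarter == "2018Q4"], 1L)
  expect_equal(qc$count[qc$quarter == "unknown"], 1L)
})
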