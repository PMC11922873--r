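test_that("generation is deterministic: same config and seed, same bytes", {
  cfg <- synthetic_config(n_cases = 250)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- suppressMessages(generate_synthetic_faers(cfg, seed = 12, dir = d1))
  g2 <- suppressMessages(generate_synthetic_faers(cfg, seed = 12, dir = d2))
  for (tb in names(g1$raw)) expect_identical(g1$raw[[tb]], g2$raw[[tb]])
  for (f in basename(g1$paths)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # a different seed changes the draw
  g3 <- suppressMessages(generate_synthetic_faers(cfg, seed = 13))
  expect_false(identical(g1$raw$reac, g3$raw$reac))
})

test_that("ground-truth pair counts equal counts recomputed from the files", {
  for (seed in c(6, 60)) {
    g <- suppressMessages(generate_synthetic_faers(
      synthetic_config(n_cases = 400), seed = seed))
    cases <- suppressMessages(deduplicate(g$raw))
    pc <- g$truth$pair_counts
    for (i in seq_len(nrow(pc))) {
      dr <- cases$drugs
      with_drug <- unique(dr$case_id[
        faersignal:::match_any_pattern(pc$drug_pattern[i], dr$name_raw,
                                       dr$active_ingredient)])
      with_pt <- unique(cases$reactions$case_id[
        cases$reactions$pt == canonical_pt(pc$pt[i])])
      n <- n_cases(cases)
      expect_equal(length(intersect(with_drug, with_pt)), pc$a[i])
      expect_equal(length(setdiff(with_drug, with_pt)), pc$b[i])
      expect_equal(length(setdiff(with_pt, with_drug)), pc$c[i])
      expect_equal(n - length(union(with_drug, with_pt)), pc$d[i])
    }
  }
})

test_that("configuration validation catches bad inputs and risky rates", {
  expect_error(synthetic_config(n_cases = 0))
  expect_error(synthetic_config(duplicate_fraction = 1))
  pv <- default_pt_vocab()
  assoc <- tibble::tibble(drug_pattern = "benserazide", pt = "Nausea",
                          lambda = 40)  # 0.11 * 40 >> 0.1
  expect_warning(synthetic_config(associations = assoc, pt_vocab = pv),
                 "rare-event")
  # probabilities above 1 after multiplication are capped with a message
  cfg <- suppressWarnings(synthetic_config(n_cases = 120,
                                           associations = assoc))
  expect_message(generate_synthetic_faers(cfg, seed = 1), "capped")
})

test_that("flowchart planting with equal targets passes everything", {
  cfg <- plant_flowchart(synthetic_config(n_cases = 300), rep(150L, 4))
  g <- suppressMessages(generate_synthetic_faers(cfg, seed = 14))
  expect_equal(unname(g$truth$stage_counts),
               c(300L, 150L, 150L, 150L, 150L))
})

test_that("at lambda = 1 the generator yields a null reporting odds ratio", {
  # median ROR across seeds for an unassociated drug-term pair
  rors <- sapply(1:200, function(s) {
    g <- suppressMessages(generate_synthetic_faers(
      estimator_recovery_config(1, n_cases = 2000), seed = 5000 + s))
    cases <- suppressMessages(deduplicate(g$raw))
    dr <- cases$drugs
    with_drug <- unique(dr$case_id[
      faersignal:::match_any_pattern("benserazide", dr$name_raw,
                                     dr$active_ingredient)])
    with_pt <- unique(cases$reactions$case_id[
      cases$reactions$pt == "On and off phenomenon"])
    n <- n_cases(cases)
    a <- length(intersect(with_drug, with_pt))
    b <- length(setdiff(with_drug, with_pt))
    cc <- length(setdiff(with_pt, with_drug))
    d <- n - a - b - cc
    ror(contingency_table(a, b, cc, d))$ror
  })
  expect_gt(median(rors), 0.85)
  expect_lt(median(rors), 1.15)
})
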