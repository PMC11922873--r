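test_that("ROR matches hand arithmetic and handles zero cells", {
  # 25*9800 / (75*100) = 245000/7500
  r <- ror(contingency_table(25, 75, 100, 9800))
  expect_equal(r$ror, 245000 / 7500, tolerance = 1e-12)
  expect_false(r$corrected)
  expect_lt(r$ci_low, r$ror); expect_gt(r$ci_high, r$ror)
  # independence: a/b = c/d
  expect_equal(ror(contingency_table(10, 90, 100, 900))$ror, 1)
  # zero cell: Haldane-Anscombe correction on all four cells
  rz <- ror(contingency_table(0, 10, 5, 100))
  expect_true(rz$corrected)
  expect_equal(rz$ror, (0.5 * 100.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_true(is.finite(rz$ci_low) && is.finite(rz$ci_high))
})

test_that("ROR invariances: transposition and cell scaling", {
  t1 <- contingency_table(12, 40, 33, 900)
  t2 <- contingency_table(33, 900, 12, 40)  # swap (a,b) with (c,d)
  expect_equal(ror(t1)$ror, 1 / ror(t2)$ror, tolerance = 1e-12)
  # scaling all cells by k preserves the point estimate, narrows the CI
  t3 <- contingency_table(12 * 5, 40 * 5, 33 * 5, 900 * 5)
  r1 <- ror(t1); r3 <- ror(t3)
  expect_equal(r3$ror, r1$ror, tolerance = 1e-12)
  expect_lt(r3$ci_high / r3$ci_low, r1$ci_high / r1$ci_low)
})

test_that("information component matches its closed form", {
  # a = E exactly: IC = 0
  t0 <- contingency_table(10, 90, 10, 90)  # E = 100*20/200 = 10
  expect_equal(bcpnn_ic(t0)$ic, 0, tolerance = 1e-12)
  # hand value: E = 1.25, IC = log2(25.5/1.75)
  ic <- bcpnn_ic(contingency_table(25, 75, 100, 9800))
  expect_equal(ic$expected, 1.25, tolerance = 1e-12)
  expect_equal(ic$ic, log2(25.5 / 1.75), tolerance = 1e-12)
  expect_equal(ic$ic025,
               log2(25.5 / 1.75) - 3.3 * 25.5^-0.5 - 2 * 25.5^-1.5,
               tolerance = 1e-12)
})

test_that("IC is strictly increasing in a at fixed E, with sign(a - E)", {
  # margins held so E = 100*100/10000 = 1 for every a
  ics <- sapply(1:30, function(a) {
    bcpnn_ic(contingency_table(a, 100 - a, 100 - a, 9800 + a))$ic
  })
  expect_true(all(diff(ics) > 0))
  set.seed(42)
  for (i in 1:50) {
    t <- contingency_table(sample(0:50, 1), sample(1:500, 1),
                           sample(1:500, 1), sample(100:5000, 1))
    ic <- bcpnn_ic(t)
    if (t$a > 0 && abs(t$a - ic$expected) > 1e-9) {
      expect_equal(sign(ic$ic), sign(t$a - ic$expected))
    }
  }
})

test_that("MGPS fit is deterministic and flags degenerate input", {
  set.seed(1)
  E <- exp(runif(300, log(0.5), log(20)))
  a <- rpois(300, E * rgamma(300, 2, 2))
  p1 <- fit_mgps_prior(data.frame(a = a, E = E))
  p2 <- fit_mgps_prior(data.frame(a = a, E = E))
  expect_true(p1$converged)
  expect_identical(unclass(p1), unclass(p2))
  # all-zero counts carry no information
  expect_warning(p0 <- fit_mgps_prior(data.frame(a = rep(0, 50),
                                                 E = rep(2, 50))),
                 "non-converged")
  expect_false(p0$converged)
  expect_error(fit_mgps_prior(data.frame(a = 1, E = 1)), "at least 2")
})

test_that("a near-point-mass prior at 1 dominates the observed count", {
  # both mixture components concentrated at lambda = 1: the posterior mean
  # of log(lambda) stays at ~0 however large the observed count
  prior <- structure(list(alpha1 = 1e6, beta1 = 1e6, alpha2 = 1e6,
                          beta2 = 1e6, p_mix = 1 - 1e-12, loglik = NA,
                          converged = TRUE, n_tables = 0L),
                     class = "mgps_prior")
  for (a in c(0, 5, 40)) {
    t <- contingency_table(a, max(1, 50 - a), 50, 900)
    expect_equal(ebgm(t, prior)$ebgm, 1, tolerance = 1e-3)
  }
})

test_that("with a diffuse prior and a >> E, EBGM approaches a/E", {
  prior <- structure(list(alpha1 = 0.1, beta1 = 0.1, alpha2 = 0.1,
                          beta2 = 0.1, p_mix = 0.5, loglik = NA,
                          converged = TRUE, n_tables = 0L),
                     class = "mgps_prior")
  t <- contingency_table(500, 500, 50, 99000)  # E ~ 5.5, a/E ~ 90
  E <- (t$a + t$b) * (t$a + t$c) / (t$a + t$b + t$c + t$d)
  eb <- ebgm(t, prior)
  expect_equal(eb$ebgm, t$a / E, tolerance = 0.05)
  expect_lt(eb$eb05, eb$ebgm); expect_gt(eb$eb95, eb$ebgm)
})

test_that("EBGM is nondecreasing in a at fixed E and shrinks toward 1", {
  set.seed(2)
  E <- exp(runif(400, log(1), log(30)))
  a <- rpois(400, E * rgamma(400, 2, 2))
  prior <- fit_mgps_prior(data.frame(a = a, E = E))
  ebs <- sapply(seq(0, 60, by = 5), function(a) {
    # margins chosen so E = 10 throughout
    ebgm(contingency_table(a, 100 - a, 1000 - a, 9000 + a), prior)$ebgm
  })
  expect_true(all(diff(ebs) > -1e-9))
})

test_that("posterior percentiles agree with a numerical-integration oracle", {
  set.seed(3)
  for (i in 1:15) {
    prior <- structure(list(alpha1 = runif(1, 0.2, 3),
                            beta1 = runif(1, 0.2, 3),
                            alpha2 = runif(1, 0.5, 6),
                            beta2 = runif(1, 0.5, 6),
                            p_mix = runif(1, 0.05, 0.95), loglik = NA,
                            converged = TRUE, n_tables = 0L),
                       class = "mgps_prior")
    a <- sample(0:80, 1)
    t <- contingency_table(a, sample(20:200, 1), sample(5:300, 1),
                           sample(1000:20000, 1))
    E <- (t$a + t$b) * (t$a + t$c) / (t$a + t$b + t$c + t$d)
    eb <- ebgm(t, prior)
    expect_lt(eb$eb05, eb$ebgm)
    expect_gt(eb$eb95, eb$ebgm)
    # independent oracle: integrate the posterior mixture density
    q <- faersignal:::mgps_posterior_weight(a, E, prior)
    dens <- function(x) {
      q * stats::dgamma(x, prior$alpha1 + a, rate = prior$beta1 + E) +
        (1 - q) * stats::dgamma(x, prior$alpha2 + a, rate = prior$beta2 + E)
    }
    cdf05 <- stats::integrate(dens, 0, eb$eb05, rel.tol = 1e-11,
                              abs.tol = 1e-13)$value
    cdf95 <- stats::integrate(dens, 0, eb$eb95, rel.tol = 1e-11,
                              abs.tol = 1e-13)$value
    expect_equal(cdf05, 0.05, tolerance = 1e-6)
    expect_equal(cdf95, 0.95, tolerance = 1e-6)
  }
})

test_that("the joint signal criterion applies all three rules", {
  sig <- function(ror, lo, hi, ic025, eb05) {
    evaluate_signal(list(ror = ror, ci_low = lo, ci_high = hi),
                    list(ic025 = ic025), list(eb05 = eb05))
  }
  # published benserazide wearing-off tuple: all rules pass
  expect_true(sig(3.03, 2.37, 3.88, 1.23, 2.44)$is_signal)
  # published benserazide dyskinesia tuple
  expect_true(sig(16.5, 14.76, 18.45, 3.75, 13.69)$is_signal)
  # boundary of the ROR >= 3 rule
  s <- sig(2.99, 1.5, 5.9, 1.0, 3.0)
  expect_false(s$is_signal)
  expect_false(s$criteria_met[["ror_rule"]])
  expect_true(s$criteria_met[["ic_rule"]])
  # each rule individually decisive
  expect_false(sig(3.5, 0.9, 9, 1, 3)$is_signal)
  expect_false(sig(3.5, 1.5, 9, -0.1, 3)$is_signal)
  expect_false(sig(3.5, 1.5, 9, 1, 1.9)$is_signal)
})

test_that("build_table counts report-level endpoint hits", {
  cohort_cases <- lapply(1:10, function(i) {
    eligible_case(as.character(i),
                  pt = if (i <= 3) "Dyskinesia" else "Tremor")
  })
  bg_cases <- lapply(11:100, function(i) {
    eligible_case(as.character(i),
                  pt = if (i <= 19) "Dystonia" else "Headache")
  })
  cohort <- filter_soc(deduplicate(bind_raw(cohort_cases)))
  bg <- deduplicate(bind_raw(bg_cases))
  t <- build_table(cohort, bg, "dyskinesia")
  expect_equal(c(t$a, t$b, t$c, t$d), c(3, 7, 9, 81))
  # an endpoint absent everywhere
  t0 <- build_table(cohort, bg, "on_off_phenomenon")
  expect_equal(c(t0$a, t0$c), c(0, 0))
  # overlap between cohort and comparator is an error
  expect_error(build_table(cohort, deduplicate(bind_raw(cohort_cases)),
                           "dyskinesia"), "disjoint")
})
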