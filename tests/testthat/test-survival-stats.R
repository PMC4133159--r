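acute_df <- function(n_dead_with, n_dead_without, n_start = 50) {
  data.frame(
    genotype = rep(c("with_TE", "without_TE"),
                   times = c(length(n_dead_with), length(n_dead_without))),
    sex = "female", condition = "stressed",
    replicate_id = seq_len(length(n_dead_with) + length(n_dead_without)),
    n_start = n_start, n_dead = c(n_dead_with, n_dead_without))
}

test_that("acute_table pools replicate counts per genotype", {
  tab <- acute_table(acute_df(c(10, 10, 10), c(10, 10, 10)))
  expect_equal(unclass(tab)[1, ], c(alive = 120L, dead = 30L))
  expect_equal(unclass(tab)[2, ], c(alive = 120L, dead = 30L))
  expect_error(acute_table(acute_df(10, 10)[0, ]), "empty")
  mixed <- acute_df(c(10), c(10)); mixed$condition <- c("stressed", "control")
  expect_error(acute_table(mixed), "usage error")
})

test_that("pooled OR equals the Mantel-Haenszel OR for homogeneous replicates", {
  d <- acute_df(c(10, 10, 10), c(25, 25, 25))
  pooled <- odds_ratio(acute_table(d))$or
  strata <- lapply(1:3, function(i)
    acute_table(d[c(i, i + 3), ])) # one with/without pair per stratum
  expect_equal(pooled, mh_odds_ratio(strata), tolerance = 1e-12)
  # independent oracle: stats::mantelhaen.test point estimate
  arr <- simplify2array(lapply(strata, unclass))
  mh <- stats::mantelhaen.test(arr, exact = FALSE, correct = FALSE)
  expect_equal(mh_odds_ratio(strata), unname(mh$estimate), tolerance = 1e-9)
})

test_that("odds ratio and Woolf interval follow the closed form", {
  tab <- matrix(c(45, 5, 25, 25), 2, 2, byrow = TRUE)
  res <- odds_ratio(tab)
  expect_equal(res$or, 9)
  se <- sqrt(1 / 45 + 1 / 5 + 1 / 25 + 1 / 25)
  expect_equal(res$ci, exp(log(9) + c(-1, 1) * qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_false(res$corrected)
  # equal proportions
  expect_equal(odds_ratio(matrix(c(40, 10, 80, 20), 2, 2, byrow = TRUE))$or, 1)
  # zero cell: Haldane-Anscombe correction keeps the OR finite
  z <- odds_ratio(matrix(c(50, 0, 25, 25), 2, 2, byrow = TRUE))
  expect_true(z$corrected)
  expect_true(is.finite(z$or))
})

test_that("OR is invariant to row and column scaling", {
  set.seed(51)
  tab <- matrix(sample(5:50, 4), 2, 2)
  base_or <- odds_ratio(tab)$or
  expect_equal(odds_ratio(tab * c(3, 1, 3, 1))$or, base_or)  # row scaled
  expect_equal(odds_ratio(t(t(tab) * c(5, 2)))$or, base_or)  # columns scaled
})

test_that("proportion tests handle degenerate input and match enumeration", {
  expect_equal(proportion_test(c(0.9, 0.8, 0.7), c(0.9, 0.8, 0.7),
                               "mannwhitney")$p, 1)
  deg <- proportion_test(c(0.9, 0.9, 0.9), c(0.5, 0.5, 0.5), "t")
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  mw <- proportion_test(c(0.9, 0.9, 0.9), c(0.5, 0.5, 0.5), "mannwhitney")
  expect_false(is.na(mw$p))
  # exact enumeration oracle at n = 3 + 3, no ties
  set.seed(52)
  for (i in 1:10) {
    a <- runif(3); b <- runif(3)
    expect_equal(proportion_test(a, b, "mannwhitney")$p,
                 enumerate_mw_p(a, b), tolerance = 1e-12)
  }
})

chronic_df <- function(counts, times = seq_along(counts) * 12,
                       replicate_id = "r1") {
  data.frame(genotype = "g", sex = "f", condition = "stressed",
             replicate_id = replicate_id, time_h = times,
             n_dead_in_interval = counts)
}

test_that("KM curve equals 1 - cumulative deaths / total without censoring", {
  rec <- rbind(chronic_df(c(2, 3, 0, 5), replicate_id = "r1"),
               chronic_df(c(1, 0, 4, 2), replicate_id = "r2"))
  km <- km_curve(rec, flies_per_replica = 20)
  expected <- 1 - cumsum(c(3, 3, 4, 7)) / 40
  expect_equal(km$surv[match(c(12, 24, 36, 48), km$time)], expected,
               tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("KM limiting cases: no deaths and immediate extinction", {
  none <- km_curve(chronic_df(c(0, 0, 0)), 20)
  expect_true(all(none$surv == 1))
  all_die <- km_curve(chronic_df(c(20, 0, 0)), 20)
  expect_equal(all_die$surv[all_die$time == 12], 0)
  expect_error(km_curve(chronic_df(c(21, 0, 0)), 20), "data error")
})

test_that("log-rank matches a hand-computed two-interval table", {
  # group A: 20 at risk, 4 die at t=12, 6 at t=24; group B: 2 then 3
  a <- chronic_df(c(4, 6), replicate_id = "a")
  b <- chronic_df(c(2, 3), replicate_id = "b")
  # hand computation of O-E and hypergeometric variance per event time
  o_e <- v <- 0
  n1 <- 20; n2 <- 20
  for (ev in list(c(4, 2), c(6, 3))) {
    d <- sum(ev); n <- n1 + n2
    o_e <- o_e + ev[1] - d * n1 / n
    v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    n1 <- n1 - ev[1]; n2 <- n2 - ev[2]
  }
  expected_chi2 <- o_e^2 / v
  lr <- logrank(a, b, flies_per_replica = 20)
  expect_equal(lr$chi2, expected_chi2, tolerance = 1e-9)
  expect_equal(lr$p, pchisq(expected_chi2, 1, lower.tail = FALSE))
})

test_that("log-rank is symmetric, non-negative, and null on identical arms", {
  a <- chronic_df(c(4, 6, 1), replicate_id = "a")
  same <- logrank(a, a, 20)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)
  b <- chronic_df(c(2, 3, 7), replicate_id = "b")
  expect_equal(logrank(a, b, 20)$chi2, logrank(b, a, 20)$chi2,
               tolerance = 1e-12)
  expect_gte(logrank(a, b, 20)$chi2, 0)
  # no events at all: unavailable
  expect_false(logrank(chronic_df(c(0, 0)), chronic_df(c(0, 0)), 20)$available)
})

test_that("log-rank power increases with the simulated hazard ratio", {
  med_chi2 <- vapply(c(1, 2, 4), function(hr) {
    chis <- vapply(1:100, function(s) {
      d <- simulate_chronic(seed = 3000 + s,
                            chronic_config(replicas = 10, hazard_ratio = 1 / hr))
      logrank(d[d$genotype == "with_TE", ], d[d$genotype == "without_TE", ],
              20)$chi2
    }, numeric(1))
    median(chis)
  }, numeric(1))
  expect_true(all(diff(med_chi2) > 0))
})

test_that("compare_survival reports OR at the final common census by default", {
  d <- simulate_chronic(seed = 60)
  cmp <- compare_survival(d[d$genotype == "with_TE", ],
                          d[d$genotype == "without_TE", ], 20)
  expect_equal(cmp$census_time_h, 168)
  expect_true(cmp$odds_ratio > 0)
  expect_true(cmp$or_ci[1] < cmp$odds_ratio & cmp$odds_ratio < cmp$or_ci[2])
  expect_s3_class(cmp, "survival_comparison")
})

test_that("design totals reproduce the published fly accounting", {
  expect_identical(design_total(9, 50, 2, 2, 2), 3600)
  expect_identical(design_total(3, 50, 2, 2, 2), 1200)
  expect_identical(design_total(20, 20, 2, 2, 2), 3200)
  expect_error(design_total(0, 50), "positive")
})
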