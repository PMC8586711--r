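# Outcome statistics: pooled summaries, reductions with bootstrap CIs,
# rank and goodness-of-fit tests, replication analysis, sensitivity sweep.

mk_records <- function(dnts_by_rep) {
  do.call(rbind, lapply(seq_along(dnts_by_rep), function(r) {
    data.frame(replication_id = r, dnt_minutes = dnts_by_rep[[r]])
  }))
}

test_that("pooled summaries use linear-interpolation quantiles", {
  s <- pooled_summary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$n, 5)
  s2 <- pooled_summary(c(rep(1, 10), rep(2, 90)))
  expect_equal(s2$p90, 2)
  expect_error(pooled_summary(numeric(0)), "no patient")
})

test_that("pooling concatenates replications rather than averaging medians", {
  reps <- list(c(10, 10, 10), rep(100, 97))
  rec <- mk_records(reps)
  pooled <- pooled_summary(rec)
  expect_equal(pooled$median, 100)   # dominated by the big replication
  mean_of_medians <- mean(vapply(reps, stats::median, numeric(1)))
  expect_false(isTRUE(all.equal(pooled$median, mean_of_medians)))
})

test_that("identical arms give zero reduction with a CI containing zero", {
  rec <- mk_records(list(rnorm(40, 50, 5), rnorm(40, 52, 5),
                         rnorm(40, 49, 5)))
  cmp <- percent_reduction_ci(rec, rec, n_boot = 200, seed = 1)
  expect_equal(cmp$median_reduction_pct, 0)
  expect_lte(cmp$ci95["median", "low"], 0)
  expect_gte(cmp$ci95["median", "high"], 0)
  expect_gt(cmp$mwu_p, 0.9)
})

test_that("an exact halving gives a degenerate 50% reduction", {
  base <- mk_records(list(c(40, 50, 60), c(45, 55, 65), c(42, 52, 62)))
  scen <- base
  scen$dnt_minutes <- scen$dnt_minutes * 0.5
  cmp <- percent_reduction_ci(base, scen, n_boot = 100, seed = 2)
  expect_equal(cmp$median_reduction_pct, 50)
  expect_equal(unname(cmp$ci95["median", ]), c(50, 50))
})

test_that("reductions are computed relative to the baseline metric", {
  base <- mk_records(list(rep(100, 10), rep(100, 10)))
  scen <- mk_records(list(rep(80, 10), rep(80, 10)))
  cmp <- percent_reduction_ci(base, scen, n_boot = 50, seed = 3)
  expect_equal(cmp$median_reduction_pct, 20)
  # a degenerate baseline IQR of zero yields an undefined IQR reduction
  expect_true(is.na(cmp$iqr_reduction_pct))
  zero <- mk_records(list(rep(0, 5), rep(0, 5)))
  expect_error(percent_reduction_ci(zero, scen, n_boot = 10),
               "baseline metric is zero")
})

test_that("bootstrap CIs cover a known median reduction at nominal rate", {
  # synthetic generator: lognormal DNTs, scenario is an exact 0.7 scaling of
  # the law, so the true median reduction is 30%
  covered <- 0L
  n_trials <- 200L
  set.seed(2024)
  for (t in seq_len(n_trials)) {
    base <- mk_records(replicate(12, exp(rnorm(50, log(50), 0.25)),
                                 simplify = FALSE))
    scen <- mk_records(replicate(12, 0.7 * exp(rnorm(50, log(50), 0.25)),
                                 simplify = FALSE))
    cmp <- percent_reduction_ci(base, scen, n_boot = 300)
    if (cmp$ci95["median", "low"] <= 30 && cmp$ci95["median", "high"] >= 30) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / n_trials, 0.90)
})

test_that("Mann-Whitney matches exact enumeration on tiny samples", {
  out <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 2 / 6, tolerance = 1e-12)
  same <- mann_whitney_u(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(same$p.value, 0.9)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("chi-square GOF matches closed-form references", {
  ex <- chi_square_gof(c(5, 5), c(5, 5))
  expect_equal(ex$statistic, 0)
  expect_equal(ex$p.value, 1)
  bad <- chi_square_gof(c(10, 0), c(5, 5))
  expect_equal(bad$statistic, 10)
  expect_equal(bad$p.value, stats::pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(bad$p.value, 0.00157, tolerance = 0.005)
  expect_error(chi_square_gof(1:3, 1:2), "equal length")
  expect_error(chi_square_gof(1:2, c(1, 0)), "positive")
})

test_that("chi-square statistic is invariant under category permutation", {
  o <- c(12, 7, 30, 9); e <- c(10, 10, 25, 12)
  set.seed(4)
  p <- sample(4)
  expect_equal(chi_square_gof(o[p], e[p])$statistic,
               chi_square_gof(o, e)$statistic)
})

test_that("replication-count analysis iterates the t half-width formula", {
  expect_equal(replications_needed(c(50, 50, 50)), 2)
  # pilot mean 50, sd 5, 5% precision at 95% confidence
  pilot <- c(45, 50, 55)
  pilot <- pilot * (50 / mean(pilot))
  pilot <- (pilot - mean(pilot)) * (5 / stats::sd(pilot)) + 50
  expect_equal(replications_needed(pilot, 0.05, 0.95), 18)
  expect_gte(replications_needed(pilot, 0.025, 0.95),
             replications_needed(pilot, 0.05, 0.95))
  expect_error(replications_needed(c(0, 0)), "mean is zero")
})

test_that("sensitivity sweep reproduces unperturbed and R1 runs exactly", {
  cfg <- default_site_configs()$site3_rural
  grid <- data.frame(role = c("decision", "decision", "tpa_prep"),
                     factor = c(1, 0.65, 1))
  tab <- sensitivity_sweep(cfg, grid, n_reps = 2, base_seed = 77)
  base <- pooled_summary(run_experiment(cfg, NULL, n_reps = 2,
                                        base_seed = 77))
  r1 <- pooled_summary(run_experiment(cfg, "R1", n_reps = 2,
                                      base_seed = 77))
  expect_equal(tab$median[1], base$median)
  expect_equal(tab$median[3], base$median)
  expect_equal(tab$median[2], r1$median)
  # shrinking a single activity cannot lengthen the median under CRN
  expect_lte(tab$median[2], tab$median[1])
  expect_error(sensitivity_sweep(cfg, data.frame(role = "nope", factor = 1),
                                 n_reps = 1), "unknown activity role")
})
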