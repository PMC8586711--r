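# Shipped site configurations and global-scale calibration.

test_that("site structure matches the documented baselines", {
  cfgs <- default_site_configs()
  expect_named(cfgs, c("site1_urban", "site2_rural", "site3_rural"))
  # only the slow rural site still transfers patients to an ED bay
  expect_true("transfer_to_ed_bay" %in% names(cfgs$site3_rural$activities))
  expect_false("transfer_to_ed_bay" %in% names(cfgs$site1_urban$activities))
  expect_false("transfer_to_ed_bay" %in% names(cfgs$site2_rural$activities))
  expect_identical(sort(cfgs$site1_urban$baseline_flags), c("P1", "P3"))
  expect_identical(sort(cfgs$site2_rural$baseline_flags), c("P1", "P3"))
  expect_length(cfgs$site3_rural$baseline_flags, 0)
  # registration is pre-door where pre-registration is baseline practice
  expect_identical(cfgs$site1_urban$activities$registration$phase, "A")
  expect_identical(cfgs$site3_rural$activities$registration$phase, "B")
  # urban site gives the bolus in imaging during regular hours already
  expect_identical(
    cfgs$site1_urban$activities$travel_imaging_to_ed$hours, "out")
  expect_identical(
    cfgs$site3_rural$activities$travel_imaging_to_ed$hours, "both")
  # rural CT technologists are on call out of hours
  expect_false("ct_callin_delay" %in% names(cfgs$site1_urban$activities))
  expect_true("ct_callin_delay" %in%
                applicable_ids(cfgs$site2_rural, "EMS", "out"))
  expect_false("ct_callin_delay" %in%
                 applicable_ids(cfgs$site2_rural, "EMS", "regular"))
})

test_that("expected treated volumes scale as 3021 : 780 : 405", {
  cfgs <- default_site_configs()
  totals <- vapply(cfgs, function(cfg)
    sum(expected_block_counts(cfg$schedule, 365, 30)), numeric(1))
  expect_equal(unname(totals / totals[[1]] * 3021), c(3021, 780, 405),
               tolerance = 1e-6)
})

test_that("every shipped distribution carries a provenance tag", {
  for (cfg in default_site_configs()) {
    for (a in cfg$activities) {
      expect_true(a$duration_regular$provenance %in% c("calibrated", "SM1"))
      expect_true(a$duration_out_of_hours$provenance %in%
                    c("calibrated", "SM1"))
    }
    expect_true(cfg$prep_in_imaging_variant$provenance %in%
                  c("calibrated", "SM1"))
  }
})

test_that("calibration recovers a known global scale", {
  cfg <- default_site_configs(calibrated = FALSE)$site2_rural
  m1 <- pooled_summary(run_experiment(cfg, NULL, n_reps = 10,
                                      base_seed = 500))$median
  # under CRN the pooled median is linear in the scale, so calibrating to
  # 0.8 x the current median must recover a scale of 0.8
  cal <- calibrate_global_scale(cfg, target_median = 0.8 * m1,
                                tolerance = 0.2, n_reps = 10, seed = 500)
  expect_true(cal$converged)
  expect_equal(cal$global_scale, 0.8, tolerance = 0.02)
  expect_lte(abs(cal$achieved_median - 0.8 * m1), 0.2)
})

test_that("a config already on target calibrates to scale ~1 immediately", {
  cfg <- default_site_configs(calibrated = FALSE)$site3_rural
  m1 <- pooled_summary(run_experiment(cfg, NULL, n_reps = 8,
                                      base_seed = 9))$median
  cal <- calibrate_global_scale(cfg, target_median = m1, tolerance = 0.5,
                                n_reps = 8, seed = 9)
  expect_true(cal$converged)
  expect_equal(cal$global_scale, 1)
  expect_equal(cal$iterations, 1L)
})

test_that("calibration is reproducible to six decimals", {
  cfg <- default_site_configs(calibrated = FALSE)$site2_rural
  c1 <- calibrate_global_scale(cfg, 35, tolerance = 0.2, n_reps = 6,
                               seed = 123)
  c2 <- calibrate_global_scale(cfg, 35, tolerance = 0.2, n_reps = 6,
                               seed = 123)
  expect_equal(round(c1$global_scale, 6), round(c2$global_scale, 6))
})

test_that("distribution tables round-trip through the CSV schema", {
  cfgs <- default_site_configs(calibrated = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_distribution_table(cfgs, path)
  loaded <- load_sm1_distributions(path, cfgs)
  for (nm in names(cfgs)) {
    for (id in names(cfgs[[nm]]$activities)) {
      a0 <- cfgs[[nm]]$activities[[id]]
      a1 <- loaded[[nm]]$activities[[id]]
      if (is.null(a0$role)) next   # table covers role-tagged activities
      expect_equal(unlist(a1$duration_regular$params),
                   unlist(a0$duration_regular$params), tolerance = 1e-12)
      expect_identical(a1$duration_regular$provenance, "SM1")
    }
    expect_equal(unlist(loaded[[nm]]$prep_in_imaging_variant$params),
                 unlist(cfgs[[nm]]$prep_in_imaging_variant$params),
                 tolerance = 1e-12)
  }
})

test_that("malformed distribution tables fail loudly, naming the row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("site,role,hours,family,params", path)
  expect_error(load_sm1_distributions(path), "empty")

  writeLines(c("site,role,hours,family,params",
               "site1_urban,decision,regular,triangular,5/10/20",
               "site1_urban,decision,out,triangular,5/bad/20"), path)
  expect_error(load_sm1_distributions(path), "row 2")

  writeLines(c("site,role,hours,family,params",
               "site9,decision,regular,triangular,5/10/20"), path)
  expect_error(load_sm1_distributions(path), "unknown site")
})

test_that("a transcribed row replaces the matching distribution", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,role,hours,family,params",
               "site1_urban,decision,regular,triangular,5/10/20"), path)
  cfgs <- load_sm1_distributions(path)
  d <- cfgs$site1_urban$activities$decision$duration_regular
  expect_identical(d$family, "triangular")
  expect_equal(unlist(d$params), c(min = 5, mode = 10, max = 20))
  expect_identical(d$provenance, "SM1")
  # out-of-hours law untouched
  expect_identical(
    cfgs$site1_urban$activities$decision$duration_out_of_hours$provenance,
    "calibrated")
})
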