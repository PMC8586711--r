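# Activity graph validation and the critical-path oracle.

test_that("shipped fixture configs validate cleanly", {
  for (cfg in default_site_configs()) {
    expect_identical(validate_config(cfg), character(0))
  }
})

test_that("predecessor cycles are reported with the offending ids", {
  acts <- list(
    activity("A", dist_constant(1), phase = "C", predecessors = "B",
             role = "decision"),
    activity("B", dist_constant(1), phase = "C", predecessors = "A",
             role = "tpa_prep"),
    activity("bolus", dist_constant(0), phase = "D", role = "bolus",
             predecessors = c("A", "B")))
  cfg <- mk_config(acts)
  report <- validate_config(cfg)
  expect_true(any(grepl("cycle", report)))
  expect_true(any(grepl("A", report) & grepl("B", report)))
})

test_that("missing roles and unknown predecessors are reported", {
  no_bolus <- mk_config(list(
    activity("x", dist_constant(1), phase = "C", role = "decision"),
    activity("y", dist_constant(1), phase = "C", role = "tpa_prep")))
  expect_true(any(grepl("role=bolus", validate_config(no_bolus))))

  ghost <- mk_config(list(
    activity("x", dist_constant(1), phase = "C", role = "decision",
             predecessors = "nowhere"),
    activity("y", dist_constant(1), phase = "C", role = "tpa_prep"),
    activity("bolus", dist_constant(0), phase = "D", role = "bolus",
             predecessors = c("x", "y"))))
  expect_true(any(grepl("nowhere", validate_config(ghost))))
})

test_that("critical path sums a serial chain", {
  cfg <- chain_config(c(5, 10))
  cp <- critical_path(cfg, "EMS", "regular",
                      c(a1 = 5, a2 = 10, bolus = 0))
  expect_equal(cp$minutes, 15)
  expect_identical(cp$path, c("a1", "a2", "bolus"))
})

test_that("critical path takes the longer of parallel branches", {
  # interpretation feeds decision and prep in parallel; bolus needs both
  acts <- list(
    activity("interpretation", dist_constant(10), phase = "C",
             role = "interpretation"),
    activity("decision", dist_constant(20), phase = "C", role = "decision",
             predecessors = "interpretation"),
    activity("tpa_prep", dist_constant(30), phase = "D", role = "tpa_prep",
             predecessors = "interpretation"),
    activity("bolus", dist_constant(0), phase = "D", role = "bolus",
             predecessors = c("decision", "tpa_prep")))
  cfg <- mk_config(acts)
  durs <- c(interpretation = 10, decision = 20, tpa_prep = 30, bolus = 0)
  cp <- critical_path(cfg, "EMS", "regular", durs)
  expect_equal(cp$minutes, 40)
  expect_identical(cp$path, c("interpretation", "tpa_prep", "bolus"))
  # agrees with exhaustive enumeration on this 4-node DAG
  expect_equal(brute_force_longest(cfg, as.list(durs)), 40)
})

test_that("all-zero durations give a zero-length path", {
  cfg <- chain_config(c(5, 10))
  cp <- critical_path(cfg, "PV", "out", c(a1 = 0, a2 = 0, bolus = 0))
  expect_equal(cp$minutes, 0)
})

test_that("missing durations for applicable activities are an error", {
  cfg <- chain_config(c(5, 10))
  expect_error(critical_path(cfg, "EMS", "regular", c(a1 = 5)),
               "missing")
})

test_that("critical path equals brute-force enumeration on random DAGs", {
  for (seed in 1:25) {
    rd <- random_dag_config(n_nodes = sample(4:11, 1), seed = seed)
    cp <- critical_path(rd$config, "EMS", "regular", rd$durations)
    bf <- brute_force_longest(rd$config, as.list(rd$durations))
    expect_equal(cp$minutes, bf)
    # the reported path realises the reported length
    expect_equal(sum(rd$durations[setdiff(cp$path, "bolus")]), cp$minutes)
  }
})

test_that("critical path is invariant to activity list order", {
  rd <- random_dag_config(n_nodes = 9, seed = 101)
  cfg <- rd$config
  set.seed(5)
  perm <- sample(length(cfg$activities))
  cfg2 <- cfg
  cfg2$activities <- cfg$activities[perm]
  expect_equal(critical_path(cfg2, "EMS", "regular", rd$durations)$minutes,
               critical_path(cfg, "EMS", "regular", rd$durations)$minutes)
})

test_that("adding a short parallel branch leaves the critical path length", {
  cfg <- chain_config(c(8, 12))   # longest path 20
  acts <- c(unname(cfg$activities), list(
    activity("side", dist_constant(5), phase = "C")))
  # side runs in parallel (no successors feeding bolus beyond existing)
  acts[[which(vapply(acts, `[[`, character(1), "id") == "bolus")]] <-
    activity("bolus", dist_constant(0), phase = "D", role = "bolus",
             predecessors = c("a2", "side"))
  cfg2 <- mk_config(acts)
  cp <- critical_path(cfg2, "EMS", "regular",
                      c(a1 = 8, a2 = 12, side = 5, bolus = 0))
  expect_equal(cp$minutes, 20)
})

test_that("non-applicable activities are dropped with rewired precedence", {
  acts <- list(
    activity("pv_only", dist_constant(7), phase = "B", applies_to = "PV"),
    activity("shared", dist_constant(5), phase = "C",
             predecessors = "pv_only"),
    activity("decision", dist_constant(2), phase = "C", role = "decision",
             predecessors = "shared"),
    activity("tpa_prep", dist_constant(3), phase = "D", role = "tpa_prep",
             predecessors = "shared"),
    activity("night_delay", dist_constant(11), phase = "C", hours = "out",
             predecessors = "shared"),
    activity("bolus", dist_constant(0), phase = "D", role = "bolus",
             predecessors = c("decision", "tpa_prep", "night_delay")))
  cfg <- mk_config(acts)
  durs <- c(pv_only = 7, shared = 5, decision = 2, tpa_prep = 3,
            night_delay = 11, bolus = 0)
  expect_equal(critical_path(cfg, "EMS", "regular", durs)$minutes, 5 + 3)
  expect_equal(critical_path(cfg, "EMS", "out", durs)$minutes, 5 + 11)
  expect_equal(critical_path(cfg, "PV", "regular", durs)$minutes, 7 + 5 + 3)
  expect_equal(critical_path(cfg, "PV", "out", durs)$minutes, 7 + 5 + 11)
})
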