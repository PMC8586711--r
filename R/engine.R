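# The discrete-event core.
#
# Each patient's treatment is an earliest-start schedule over the applicable
# activity DAG. The only cross-patient interaction is the hospital-wide
# stroke protocol: a capacity-one token held from the first post-door
# activity until the start of the bolus, granted FIFO by door time. At the
# modelled volumes (~100 treated patients/year) contention is rare, but the
# single-activation constraint is part of the model.
#
# Randomness is organised in per-patient substreams: patient i of
# replication r under base seed s draws from a stream seeded by a
# deterministic mix of (s, r, i), with one uniform reserved for the pathway
# draw and one per activity of the *base* inventory (in the order frozen in
# config$rng_ids). Scenario transformations delete or rescale activities but
# never reshuffle the uniforms, so baseline and scenario runs are coupled by
# common random numbers: a scaled activity yields exactly the scaled draw,
# and a deleted activity's uniform is simply unused.

.MIX_MOD <- 2147483647

# Deterministic seed mixing; all intermediates stay below 2^53 so doubles
# carry them exactly, and the result fits a 32-bit integer seed.
mix_seed <- function(...) {
  s <- 0
  for (x in c(...)) {
    s <- (s * 69069 + (as.numeric(x) %% .MIX_MOD) + 1) %% .MIX_MOD
  }
  as.integer(s)
}

# Schedule one patient over a prebuilt graph. durations are aligned with
# g$ids. Returns needle time (start of bolus) and the start/finish vectors.
.schedule_patient <- function(g, durations, entry_time) {
  n <- length(g$ids)
  start <- numeric(n)
  finish <- numeric(n)
  for (v in seq_len(n)) {
    pidx <- g$preds_idx[[v]]
    start[v] <- if (length(pidx)) max(entry_time, finish[pidx]) else entry_time
    finish[v] <- start[v] + durations[v]
  }
  list(start = start, finish = finish, needle = start[g$bolus])
}

#' Execute a single patient
#'
#' Runs one patient through the applicable activity DAG with earliest-start
#' semantics: every activity starts once all its predecessors have finished,
#' and nothing starts before the stroke-protocol token is free. The
#' door-to-needle time is the start of the bolus activity minus the door
#' time. Durations are drawn from the current RNG state.
#'
#' @param config A valid [site_config()].
#' @param pathway `"EMS"` or `"PV"`.
#' @param hours_class `"regular"` or `"out"`.
#' @param door_time Arrival time in minutes.
#' @param token_free Time at which the stroke-protocol token becomes
#'   available (`-Inf` for an idle hospital).
#' @return List with `dnt`, `needle_time`, `token_free` (the new token
#'   release time), and `log` (a data frame of activity start/finish times).
#' @export
execute_patient <- function(config, pathway, hours_class, door_time,
                            token_free = -Inf) {
  assert_valid_config(config)
  g <- build_graph(config, pathway, hours_class)
  u <- stats::runif(length(g$ids))
  durations <- config$duration_scale *
    vapply(seq_along(g$ids), function(v) dist_quantile(g$dists[[v]], u[v]),
           numeric(1L))
  entry <- max(door_time, token_free)
  sched <- .schedule_patient(g, durations, entry)
  list(dnt = sched$needle - door_time,
       needle_time = sched$needle,
       token_free = sched$needle,
       log = data.frame(activity = g$ids, start = sched$start,
                        finish = sched$finish))
}

#' Run one replication
#'
#' Simulates every patient whose door time falls within the horizon; patients
#' arriving before the horizon end always complete (no censoring, no warm-up
#' discard). All patients are treated. Deterministic given `seed` and
#' `replication`.
#'
#' @param config A valid [site_config()].
#' @param scenario Optional [scenario_spec()] (or scenario string) applied to
#'   the configuration before running.
#' @param horizon_days Replication length in days (default 365).
#' @param seed Base seed for the experiment.
#' @param replication Replication index (>= 1); replications use independent
#'   substreams derived from `(seed, replication)`.
#' @param keep_log If `TRUE`, attach per-activity start/finish times.
#' @param independent_arrivals If `TRUE`, scenario runs draw fresh arrival
#'   streams instead of reusing the baseline stream (the default couples
#'   scenario and baseline runs by common random numbers).
#' @return Data frame of patient records: `patient_id`, `replication_id`,
#'   `pathway`, `hours_class`, `door_minute`, `needle_minute`, `dnt_minutes`;
#'   with attribute `activity_log` when `keep_log = TRUE`.
#' @export
run_replication <- function(config, scenario = NULL, horizon_days = 365,
                            seed = 1L, replication = 1L, keep_log = FALSE,
                            independent_arrivals = FALSE) {
  if (!is.null(scenario)) {
    config <- apply_scenarios(config, as_scenario_spec(scenario))
  }
  assert_valid_config(config)

  arrival_salt <- if (independent_arrivals) {
    sum(utf8ToInt(paste(config$applied_scenarios, collapse = "+")))
  } else 0L
  set.seed(mix_seed(seed, replication, 0L, arrival_salt))
  doors <- generate_arrivals(config$schedule, horizon_days)
  n <- length(doors)

  graphs <- list(
    EMS = list(regular = build_graph(config, "EMS", "regular"),
               out = build_graph(config, "EMS", "out")),
    PV = list(regular = build_graph(config, "PV", "regular"),
              out = build_graph(config, "PV", "out")))
  # map each graph's nodes into the frozen uniform-stream slots
  slot_idx <- lapply(graphs, lapply, function(g) match(g$ids, config$rng_ids))
  n_slots <- length(config$rng_ids)
  dscale <- config$duration_scale

  pathway <- character(n)
  hours <- character(n)
  needle <- numeric(n)
  token_free <- -Inf
  logs <- if (keep_log) vector("list", n)

  for (i in seq_len(n)) {
    set.seed(mix_seed(seed, replication, i))
    u <- stats::runif(1L + n_slots)
    pw <- if (u[1L] < config$p_ems) "EMS" else "PV"
    hr <- classify_hours(doors[i])
    g <- graphs[[pw]][[hr]]
    ui <- u[1L + slot_idx[[pw]][[hr]]]
    durations <- dscale * vapply(
      seq_along(g$ids), function(v) dist_quantile(g$dists[[v]], ui[v]),
      numeric(1L))
    entry <- max(doors[i], token_free)
    sched <- .schedule_patient(g, durations, entry)
    pathway[i] <- pw
    hours[i] <- hr
    needle[i] <- sched$needle
    token_free <- sched$needle
    if (keep_log) {
      logs[[i]] <- data.frame(patient_id = i, activity = g$ids,
                              start = sched$start, finish = sched$finish)
    }
  }

  rec <- data.frame(
    patient_id = seq_len(n),
    replication_id = rep(as.integer(replication), n),
    pathway = pathway,
    hours_class = hours,
    door_minute = doors,
    needle_minute = needle,
    dnt_minutes = needle - doors
  )
  if (keep_log) {
    attr(rec, "activity_log") <- do.call(rbind, logs)
  }
  rec
}

#' Run a replicated experiment
#'
#' Runs `n_reps` independent one-year replications of a site configuration
#' under an optional scenario and pools the patient records. Replication `r`
#' uses a substream derived from `(base_seed, r)`, so pooled output is
#' invariant to execution order and byte-identical across reruns.
#'
#' @inheritParams run_replication
#' @param n_reps Number of replications (default 30).
#' @param base_seed Base seed for all randomness in the experiment.
#' @return An object of class `dnt_experiment`: a list with `records` (the
#'   pooled patient data frame), `site_id`, `scenario_label`, `n_reps`,
#'   `horizon_days`, and `base_seed`.
#' @examples
#' cfg <- default_site_configs()$site3_rural
#' ex <- run_experiment(cfg, n_reps = 2, base_seed = 7)
#' summary(ex)
#' @export
run_experiment <- function(config, scenario = NULL, n_reps = 30,
                           horizon_days = 365, base_seed = 1L,
                           keep_log = FALSE, independent_arrivals = FALSE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(scenario)) {
    scenario <- as_scenario_spec(scenario)
    config <- apply_scenarios(config, scenario)
  }
  assert_valid_config(config)
  reps <- lapply(seq_len(n_reps), function(r) {
    run_replication(config, scenario = NULL, horizon_days = horizon_days,
                    seed = base_seed, replication = r, keep_log = keep_log,
                    independent_arrivals = independent_arrivals)
  })
  records <- do.call(rbind, reps)
  rownames(records) <- NULL
  out <- list(records = records,
              site_id = config$site_id,
              scenario_label = scenario_label(config$applied_scenarios),
              applied_scenarios = config$applied_scenarios,
              n_reps = as.integer(n_reps),
              horizon_days = horizon_days,
              base_seed = as.integer(base_seed))
  if (keep_log) {
    out$activity_log <- do.call(rbind, lapply(seq_along(reps), function(r) {
      lg <- attr(reps[[r]], "activity_log")
      if (!is.null(lg) && nrow(lg)) cbind(replication_id = r, lg)
    }))
  }
  structure(out, class = "dnt_experiment")
}

#' @export
print.dnt_experiment <- function(x, ...) {
  s <- pooled_summary(x)
  cat(sprintf("<dnt_experiment %s | %s | %d replications x %g days>\n",
              x$site_id, x$scenario_label, x$n_reps, x$horizon_days))
  cat(sprintf("  n = %d patients | median DNT %.1f (IQR %.1f-%.1f) | P90 %.1f min\n",
              s$n, s$median, s$q25, s$q75, s$p90))
  invisible(x)
}

#' @export
summary.dnt_experiment <- function(object, ...) {
  pooled_summary(object)
}
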