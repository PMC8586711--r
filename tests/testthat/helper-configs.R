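# Shared builders for small synthetic configurations and an independent
# brute-force longest-path oracle.

test_schedule <- function(rate = 0.01, scale = 1) {
  arrival_schedule(rep(rate, 12), scale = scale)
}

# Minimal valid config wrapper: caller supplies activities (must include
# decision / tpa_prep / bolus roles on every applicable graph).
mk_config <- function(acts, site_id = "test", p_ems = 0.8,
                      schedule = test_schedule(), flags = character(),
                      variant = NULL, duration_scale = 1) {
  site_config(site_id, acts, schedule, p_ems = p_ems,
              baseline_flags = flags, prep_in_imaging_variant = variant,
              duration_scale = duration_scale)
}

# A serial chain of constant-duration activities ending in a bolus. The two
# activities immediately before the bolus carry the decision and tpa_prep
# roles so the config validates.
chain_config <- function(minutes, ...) {
  stopifnot(length(minutes) >= 2L)
  n <- length(minutes)
  ids <- paste0("a", seq_len(n))
  roles <- rep(list(NULL), n)
  roles[[n - 1L]] <- "decision"
  roles[[n]] <- "tpa_prep"
  acts <- lapply(seq_len(n), function(i) {
    activity(ids[i], dist_constant(minutes[i]), phase = "C",
             predecessors = if (i > 1L) ids[i - 1L] else character(),
             role = roles[[i]])
  })
  acts <- c(acts, list(activity("bolus", dist_constant(0), phase = "D",
                                role = "bolus", predecessors = ids[n])))
  mk_config(acts, ...)
}

# Random constant-duration DAG over n nodes (node i may depend on nodes
# < i), always ending in a bolus that depends on the sink nodes.
random_dag_config <- function(n_nodes, seed) {
  set.seed(seed)
  ids <- paste0("n", seq_len(n_nodes))
  roles <- rep(list(NULL), n_nodes)
  roles[[sample(n_nodes, 1L)]] <- "decision"
  free <- setdiff(seq_len(n_nodes), which(!vapply(roles, is.null,
                                                  logical(1L))))
  roles[[sample(free, 1L)]] <- "tpa_prep"
  durs <- round(stats::runif(n_nodes, 0, 20), 3)
  acts <- lapply(seq_len(n_nodes), function(i) {
    preds <- if (i == 1L) character() else {
      k <- sample(0:min(3L, i - 1L), 1L)
      if (k > 0L) ids[sample(i - 1L, k)] else character()
    }
    activity(ids[i], dist_constant(durs[i]), phase = "C",
             predecessors = preds, role = roles[[i]])
  })
  used <- unique(unlist(lapply(acts, `[[`, "predecessors")))
  sinks <- setdiff(ids, used)
  acts <- c(acts, list(activity("bolus", dist_constant(0), phase = "D",
                                role = "bolus", predecessors = sinks)))
  cfg <- mk_config(acts)
  durations <- c(durs, 0)
  names(durations) <- c(ids, "bolus")
  list(config = cfg, durations = durations)
}

# Independent oracle: enumerate every path into `target` over the declared
# predecessor lists and return the maximum total duration of the strict
# predecessors (the bolus itself contributes nothing).
brute_force_longest <- function(config, durations, target = "bolus") {
  preds_of <- lapply(config$activities, `[[`, "predecessors")
  longest_into <- function(id) {
    ps <- preds_of[[id]]
    if (!length(ps)) return(0)
    max(vapply(ps, function(p) longest_into(p) + durations[[p]], numeric(1L)))
  }
  longest_into(target)
}

# Replace every duration distribution in a config with the constant equal to
# a supplied named vector (or each distribution's median).
constantify <- function(config, values = NULL) {
  for (id in names(config$activities)) {
    a <- config$activities[[id]]
    v <- if (!is.null(values)) values[[id]] else
      dist_median(a$duration_regular)
    a$duration_regular <- dist_constant(v)
    a$duration_out_of_hours <- dist_constant(
      if (!is.null(values)) values[[id]] else v)
    config$activities[[id]] <- a
  }
  config
}
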