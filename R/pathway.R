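# The domain model: treatment activities, their precedence graph, pathway and
# hours applicability, and whole-site configurations.
#
# An activity graph is declared once per site over the full activity
# inventory. The graph actually executed for one patient depends on the
# patient's pathway (EMS or PV) and hours class (regular or out-of-hours):
# non-applicable activities are dropped and their successors are rewired to
# the dropped activity's own predecessors (transitively). Pre-arrival
# (phase A) activities contribute zero post-door time for EMS patients, in
# line with always-received pre-notification; for PV patients a phase-A tag
# simply means the activity was moved ahead of the door for EMS only, so PV
# keeps it in the post-door graph.

.PHASES <- c("A", "B", "C", "D")
.PATHWAYS <- c("EMS", "PV")
.HOURS <- c("regular", "out")
.ROLES <- c("transfer_to_ed_bay", "registration", "travel_to_imaging",
            "ncct", "cta", "labs", "neuro_assessment", "interpretation",
            "decision", "tpa_prep", "travel_imaging_to_ed", "bolus",
            "ct_callin_delay", "triage", "recognition", "protocol_activation",
            "team_activation", "pre_notification")

#' Define one treatment activity
#'
#' One node of a site's treatment activity graph.
#'
#' @param id Short unique token identifying the activity within a site.
#' @param duration A [duration_dist()] for the activity time during regular
#'   hours (Monday-Friday 08:00-16:00).
#' @param phase Process phase: `"A"` pre-arrival, `"B"` arrival, `"C"`
#'   imaging and treatment decision, `"D"` treatment.
#' @param applies_to `"EMS"`, `"PV"`, or `"both"`: which arrival pathway(s)
#'   include the activity.
#' @param hours `"regular"`, `"out"`, or `"both"`: which hours class(es)
#'   include the activity (e.g. a CT-technologist call-in delay exists only
#'   out of hours at rural sites).
#' @param predecessors Character vector of activity ids that must finish
#'   before this activity can start.
#' @param duration_out Optional [duration_dist()] used out of hours;
#'   defaults to `duration` (same law in both hours classes).
#' @param role Optional semantic tag (e.g. `"decision"`, `"tpa_prep"`,
#'   `"bolus"`) that scenario transformations and reports key on.
#' @param label Free-text description.
#' @return An object of class `dnt_activity`.
#' @export
activity <- function(id, duration, phase, applies_to = "both",
                     hours = "both", predecessors = character(),
                     duration_out = NULL, role = NULL, label = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  phase <- match.arg(phase, .PHASES)
  applies_to <- match.arg(applies_to, c("both", .PATHWAYS))
  hours <- match.arg(hours, c("both", .HOURS))
  if (!is_duration_dist(duration)) stop("duration must be a duration_dist")
  if (is.null(duration_out)) duration_out <- duration
  if (!is_duration_dist(duration_out)) {
    stop("duration_out must be a duration_dist")
  }
  if (!is.null(role)) role <- match.arg(role, .ROLES)
  structure(
    list(id = id, label = label, phase = phase, applies_to = applies_to,
         hours = hours, predecessors = as.character(predecessors),
         duration_regular = duration, duration_out_of_hours = duration_out,
         role = role),
    class = "dnt_activity"
  )
}

#' Assemble a site configuration
#'
#' Bundles a site's activity graph, arrival process, pathway mix, and
#' baseline process flags into the object every simulation run starts from.
#'
#' @param site_id Site token, e.g. `"site1_urban"`.
#' @param activities List of [activity()] objects.
#' @param schedule An [arrival_schedule()].
#' @param p_ems Probability that a patient arrives by ambulance (EMS);
#'   the remainder arrive by private vehicle (PV). Default 0.80.
#' @param baseline_flags Subset of `c("P1", "P2", "P3")` naming process
#'   changes the site already runs at baseline; applying such a scenario is
#'   a no-op ("current baseline").
#' @param prep_in_imaging_variant [duration_dist()] for the shortened tPA
#'   preparation used when the bolus is given in the imaging area (scenario
#'   P2).
#' @param duration_scale Global multiplier applied to every sampled duration;
#'   set by [calibrate_global_scale()] so the baseline median DNT matches a
#'   site's observed median.
#' @return An object of class `site_config`.
#' @export
site_config <- function(site_id, activities, schedule, p_ems = 0.80,
                        baseline_flags = character(),
                        prep_in_imaging_variant = NULL,
                        duration_scale = 1) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  if (!all(vapply(activities, inherits, logical(1L), "dnt_activity"))) {
    stop("activities must be a list of activity() objects")
  }
  ids <- vapply(activities, `[[`, character(1L), "id")
  names(activities) <- ids
  if (!inherits(schedule, "arrival_schedule")) {
    stop("schedule must be an arrival_schedule")
  }
  baseline_flags <- as.character(baseline_flags)
  bad <- setdiff(baseline_flags, c("P1", "P2", "P3"))
  if (length(bad)) {
    stop("baseline_flags may only contain P1, P2, P3 (got: ",
         paste(bad, collapse = ", "), ")")
  }
  if (!is.null(prep_in_imaging_variant) &&
      !is_duration_dist(prep_in_imaging_variant)) {
    stop("prep_in_imaging_variant must be a duration_dist")
  }
  structure(
    list(site_id = site_id, activities = activities, schedule = schedule,
         p_ems = p_ems, baseline_flags = baseline_flags,
         prep_in_imaging_variant = prep_in_imaging_variant,
         duration_scale = duration_scale,
         # frozen uniform-stream slots: one per activity of the *base*
         # inventory, preserved by scenario edits so common random numbers
         # line up across configurations
         rng_ids = sort(ids),
         applied_scenarios = character()),
    class = "site_config"
  )
}

activity_ids <- function(config) names(config$activities)

# Find activity ids carrying a role, optionally restricted to a pathway.
role_ids <- function(config, role, pathway = NULL) {
  keep <- vapply(config$activities, function(a) {
    identical(a$role, role) &&
      (is.null(pathway) || a$applies_to %in% c("both", pathway))
  }, logical(1L))
  names(config$activities)[keep]
}

applicable_ids <- function(config, pathway, hours) {
  pathway <- match.arg(pathway, .PATHWAYS)
  hours <- match.arg(hours, .HOURS)
  keep <- vapply(config$activities, function(a) {
    a$applies_to %in% c("both", pathway) &&
      a$hours %in% c("both", hours) &&
      # phase-A work happens before the door for EMS patients
      !(pathway == "EMS" && a$phase == "A")
  }, logical(1L))
  names(config$activities)[keep]
}

# Kahn topological sort over the full declared graph; NULL if cyclic.
.topo_order <- function(ids, preds) {
  indeg <- vapply(preds, length, integer(1L))
  order <- character(0)
  queue <- ids[indeg == 0L]
  indeg <- indeg  # named by ids
  names(indeg) <- ids
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    succs <- ids[vapply(ids, function(w) v %in% preds[[w]], logical(1L))]
    for (w in succs) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) == length(ids)) order else NULL
}

# Build the executable DAG for one (pathway, hours) combination: applicable
# activities with predecessors transitively rewired through dropped nodes.
# Returns ids in topological order, integer predecessor lists, the active
# duration distribution per node, and the bolus index.
build_graph <- function(config, pathway, hours) {
  ids_all <- activity_ids(config)
  preds_all <- lapply(config$activities, `[[`, "predecessors")
  keep <- applicable_ids(config, pathway, hours)

  eff <- new.env(parent = emptyenv())
  eff_preds <- function(id) {
    if (!is.null(eff[[id]])) return(eff[[id]])
    eff[[id]] <- character(0)  # cycle guard; graphs are validated acyclic
    out <- character(0)
    for (p in preds_all[[id]]) {
      out <- c(out, if (p %in% keep) p else eff_preds(p))
    }
    eff[[id]] <- unique(out)
    eff[[id]]
  }
  preds <- lapply(keep, eff_preds)
  names(preds) <- keep

  topo <- .topo_order(keep, preds)
  if (is.null(topo)) {
    stop("activity graph for pathway ", pathway, ", hours ", hours,
         " contains a cycle")
  }
  preds <- preds[topo]
  dists <- lapply(config$activities[topo], function(a) {
    if (hours == "out") a$duration_out_of_hours else a$duration_regular
  })
  roles <- vapply(config$activities[topo], function(a) {
    if (is.null(a$role)) "" else a$role
  }, character(1L))
  bolus <- which(roles == "bolus")
  list(ids = topo,
       preds_idx = lapply(preds, match, topo),
       dists = dists,
       roles = roles,
       bolus = if (length(bolus) == 1L) bolus else NA_integer_)
}

#' Validate a site configuration
#'
#' Checks every structural invariant the simulation engine relies on and
#' returns all violations found (an empty character vector means the
#' configuration is usable).
#'
#' @param config A [site_config()].
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "site_config")) {
    return("not a site_config object")
  }
  out <- character(0)
  ids <- activity_ids(config)
  if (anyDuplicated(ids)) {
    out <- c(out, paste0("duplicate activity ids: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (a in config$activities) {
    missing <- setdiff(a$predecessors, ids)
    if (length(missing)) {
      out <- c(out, paste0("activity '", a$id,
                           "' references unknown predecessor(s): ",
                           paste(missing, collapse = ", ")))
    }
  }
  if (length(out)) return(out)  # graph checks need a well-formed id space

  preds_all <- lapply(config$activities, `[[`, "predecessors")
  if (is.null(.topo_order(ids, preds_all))) {
    # name the ids still locked in a cycle after peeling the acyclic part
    indeg_ids <- ids
    repeat {
      removable <- indeg_ids[vapply(indeg_ids, function(v) {
        !length(intersect(preds_all[[v]], indeg_ids))
      }, logical(1L))]
      if (!length(removable)) break
      indeg_ids <- setdiff(indeg_ids, removable)
    }
    out <- c(out, paste0("predecessor cycle involving: ",
                         paste(indeg_ids, collapse = ", ")))
    return(out)
  }

  for (pw in .PATHWAYS) {
    for (hr in .HOURS) {
      keep <- applicable_ids(config, pw, hr)
      for (need in c("bolus", "decision", "tpa_prep")) {
        n <- sum(vapply(config$activities[keep], function(a) {
          identical(a$role, need)
        }, logical(1L)))
        if (n != 1L) {
          out <- c(out, sprintf(
            "pathway %s, hours %s: expected exactly one role=%s activity, found %d",
            pw, hr, need, n))
        }
      }
    }
  }
  if (!(config$p_ems > 0 && config$p_ems < 1)) {
    out <- c(out, "p_ems must lie strictly between 0 and 1")
  }
  if (!(config$schedule$scale > 0)) {
    out <- c(out, "arrival scale must be positive")
  }
  if (!(config$duration_scale > 0)) {
    out <- c(out, "duration_scale must be positive")
  }
  out
}

assert_valid_config <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid site_config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(config)
}

#' Longest door-to-bolus path under fixed durations
#'
#' Deterministic critical-path oracle: the longest path through the
#' applicable activity DAG from the door to the start of the tPA bolus,
#' with each activity given a fixed duration. When every duration
#' distribution is constant and no patient queues for the stroke protocol,
#' the engine's DNT equals this value; reductions off the critical path
#' cannot shorten DNT.
#'
#' @param config A valid [site_config()].
#' @param pathway `"EMS"` or `"PV"`.
#' @param hours `"regular"` or `"out"`.
#' @param fixed_durations Named numeric vector of minutes covering every
#'   applicable activity (the bolus itself contributes no time: DNT ends at
#'   its start).
#' @return List with `minutes` (path length) and `path` (activity ids of one
#'   maximising chain, ending in the bolus).
#' @export
critical_path <- function(config, pathway, hours, fixed_durations) {
  assert_valid_config(config)
  g <- build_graph(config, pathway, hours)
  missing <- setdiff(g$ids, names(fixed_durations))
  if (length(missing)) {
    stop("fixed_durations missing for applicable activity(ies): ",
         paste(missing, collapse = ", "))
  }
  dur <- as.numeric(fixed_durations[g$ids])
  n <- length(g$ids)
  finish <- numeric(n)   # longest path length through and including node
  back <- integer(n)     # argmax predecessor for path recovery
  for (v in seq_len(n)) {
    pidx <- g$preds_idx[[v]]
    base <- 0
    back[v] <- 0L
    if (length(pidx)) {
      base <- max(finish[pidx])
      back[v] <- pidx[which.max(finish[pidx])]
    }
    finish[v] <- base + dur[v]
  }
  b <- g$bolus
  pidx <- g$preds_idx[[b]]
  start_bolus <- if (length(pidx)) max(finish[pidx]) else 0
  path <- g$ids[b]
  v <- if (length(pidx)) pidx[which.max(finish[pidx])] else 0L
  while (v != 0L) {
    path <- c(g$ids[v], path)
    v <- back[v]
  }
  list(minutes = start_bolus, path = path)
}

#' @export
print.site_config <- function(x, ...) {
  cat(sprintf("<site_config '%s'>\n", x$site_id))
  cat(sprintf("  activities: %d  | p_ems: %.2f | arrival scale: %.4f\n",
              length(x$activities), x$p_ems, x$schedule$scale))
  cat(sprintf("  baseline flags: %s\n",
              if (length(x$baseline_flags))
                paste(x$baseline_flags, collapse = ", ") else "(none)"))
  if (length(x$applied_scenarios)) {
    cat(sprintf("  applied scenarios: %s\n",
                paste(x$applied_scenarios, collapse = "+")))
  }
  if (x$duration_scale != 1) {
    cat(sprintf("  duration scale: %.6f\n", x$duration_scale))
  }
  invisible(x)
}

#' @export
print.dnt_activity <- function(x, ...) {
  cat(sprintf("<activity '%s' phase %s [%s/%s]%s <- {%s}>\n  regular: %s\n",
              x$id, x$phase, x$applies_to, x$hours,
              if (is.null(x$role)) "" else paste0(" role=", x$role),
              paste(x$predecessors, collapse = ", "),
              format(x$duration_regular)))
  invisible(x)
}
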