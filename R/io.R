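# Configuration file format, result serialization and report rendering.
#
# Site configurations round-trip through a structured schema (YAML or JSON
# by file extension) with top-level keys: schema_version, site, arrivals,
# p_ems, baseline_flags, prep_in_imaging_variant, activities. Results are
# plain CSV: desk-scale data, diff-friendly.

.CONFIG_SCHEMA_VERSION <- 1L

dist_to_list <- function(d) {
  list(family = d$family,
       params = if (d$family == "empirical") as.list(d$params$atoms) else
         lapply(d$params, identity),
       lower_bound = d$lower_bound,
       provenance = d$provenance)
}

list_to_dist <- function(x, where) {
  for (key in c("family", "params")) {
    if (is.null(x[[key]])) {
      stop("config error at ", where, ": missing key '", key, "'")
    }
  }
  params <- if (identical(x$family, "empirical")) {
    as.numeric(unlist(x$params))
  } else {
    p <- unlist(x$params)
    nm <- names(p)
    p <- suppressWarnings(as.numeric(p))
    if (anyNA(p)) stop("config error at ", where, ": non-numeric parameter")
    names(p) <- nm
    p
  }
  tryCatch(
    duration_dist(x$family, params,
                  lower_bound = if (is.null(x$lower_bound)) 0 else
                    as.numeric(x$lower_bound),
                  provenance = if (is.null(x$provenance)) "unspecified" else
                    x$provenance),
    error = function(e) {
      stop("config error at ", where, ": ", conditionMessage(e))
    })
}

config_to_list <- function(config) {
  stopifnot(inherits(config, "site_config"))
  list(
    schema_version = .CONFIG_SCHEMA_VERSION,
    site = config$site_id,
    p_ems = config$p_ems,
    duration_scale = config$duration_scale,
    baseline_flags = as.list(config$baseline_flags),
    arrivals = list(block_rates = as.list(config$schedule$block_rates),
                    scale = config$schedule$scale),
    prep_in_imaging_variant = if (is.null(config$prep_in_imaging_variant))
      NULL else dist_to_list(config$prep_in_imaging_variant),
    activities = lapply(unname(config$activities), function(a) {
      list(id = a$id, label = a$label, phase = a$phase,
           applies_to = a$applies_to, hours = a$hours,
           role = a$role,
           predecessors = as.list(a$predecessors),
           duration_regular = dist_to_list(a$duration_regular),
           duration_out_of_hours =
             if (identical(a$duration_regular, a$duration_out_of_hours))
               NULL else dist_to_list(a$duration_out_of_hours))
    })
  )
}

list_to_config <- function(x, source = "config") {
  sv <- x$schema_version
  if (is.null(sv)) stop("config error: missing key 'schema_version'")
  if (floor(as.numeric(sv)) != .CONFIG_SCHEMA_VERSION) {
    stop("config schema version ", sv, " not supported (expected ",
         .CONFIG_SCHEMA_VERSION, ")")
  }
  for (key in c("site", "arrivals", "activities")) {
    if (is.null(x[[key]])) stop("config error: missing key '", key, "'")
  }
  if (is.null(x$arrivals$block_rates)) {
    stop("config error: missing key 'arrivals.block_rates'")
  }
  rates_raw <- unlist(x$arrivals$block_rates)
  rates <- suppressWarnings(as.numeric(rates_raw))
  if (anyNA(rates)) {
    stop("config error at arrivals.block_rates[",
         which(is.na(rates))[1L], "]: expected a number, got '",
         rates_raw[which(is.na(rates))[1L]], "'")
  }
  schedule <- arrival_schedule(
    rates, scale = if (is.null(x$arrivals$scale)) 1 else
      as.numeric(x$arrivals$scale))
  acts <- lapply(seq_along(x$activities), function(i) {
    a <- x$activities[[i]]
    where <- paste0("activities[", i, "]")
    for (key in c("id", "phase", "duration_regular")) {
      if (is.null(a[[key]])) {
        stop("config error at ", where, ": missing key '", key, "'")
      }
    }
    activity(
      id = a$id,
      duration = list_to_dist(a$duration_regular,
                              paste0(where, ".duration_regular")),
      phase = a$phase,
      applies_to = if (is.null(a$applies_to)) "both" else a$applies_to,
      hours = if (is.null(a$hours)) "both" else a$hours,
      predecessors = as.character(unlist(a$predecessors)),
      duration_out = if (is.null(a$duration_out_of_hours)) NULL else
        list_to_dist(a$duration_out_of_hours,
                     paste0(where, ".duration_out_of_hours")),
      role = a$role,
      label = if (is.null(a$label)) a$id else a$label)
  })
  site_config(
    site_id = x$site,
    activities = acts,
    schedule = schedule,
    p_ems = if (is.null(x$p_ems)) 0.80 else as.numeric(x$p_ems),
    baseline_flags = as.character(unlist(x$baseline_flags)),
    prep_in_imaging_variant = if (is.null(x$prep_in_imaging_variant)) NULL
      else list_to_dist(x$prep_in_imaging_variant, "prep_in_imaging_variant"),
    duration_scale = if (is.null(x$duration_scale)) 1 else
      as.numeric(x$duration_scale))
}

#' Read and write site configurations
#'
#' Site configurations serialize to YAML (`.yaml`/`.yml`) or JSON (`.json`);
#' writing then reading reproduces an equivalent configuration. Schema
#' violations are reported with the offending key path. Files written by a
#' newer major schema version are refused.
#'
#' @param path File path; the extension selects the format.
#' @param config A valid [site_config()] (for `write_config`).
#' @return `read_config` returns a [site_config()]; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- list_to_config(x, source = path)
  problems <- validate_config(cfg)
  if (length(problems)) {
    stop("config file ", path, " is invalid:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  assert_valid_config(config)
  x <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' Render a scenario comparison report
#'
#' Builds the median-DNT results table: one row for the baseline and one
#' per requested scenario, with pooled n, median, IQR endpoints, 90th
#' percentile, Mann-Whitney p-value against baseline, and the median
#' reduction with its bootstrap confidence interval. Scenarios that are
#' entirely part of the site's baseline render as `"Current baseline"`.
#'
#' @param baseline A `dnt_experiment` for the unmodified configuration.
#' @param scenario_results Named list of `dnt_experiment`s (names are the
#'   scenario labels); may be empty.
#' @param config The [site_config()] the experiments were run on (used to
#'   recognise baseline no-ops).
#' @param n_boot Bootstrap draws for the reduction confidence intervals.
#' @param seed Seed for the bootstrap.
#' @return Data frame with columns `scenario`, `n`, `median`, `q25`, `q75`,
#'   `p90`, `mwu_p`, `median_reduction_pct`, `ci_low`, `ci_high`, `note`.
#' @export
render_report <- function(baseline, scenario_results = list(), config = NULL,
                          n_boot = 2000, seed = 1L) {
  stopifnot(inherits(baseline, "dnt_experiment"))
  sites <- vapply(c(list(baseline), unname(scenario_results)),
                  `[[`, character(1L), "site_id")
  if (length(unique(sites)) != 1L) {
    stop("all experiments in a report must come from the same site (got: ",
         paste(unique(sites), collapse = ", "), ")")
  }
  s0 <- pooled_summary(baseline)
  rows <- list(data.frame(
    scenario = "baseline", n = s0$n, median = s0$median, q25 = s0$q25,
    q75 = s0$q75, p90 = s0$p90, mwu_p = NA_real_,
    median_reduction_pct = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    note = ""))
  for (nm in names(scenario_results)) {
    ex <- scenario_results[[nm]]
    # labels that are not scenario strings (e.g. file stems) never no-op
    codes <- tryCatch(as_scenario_spec(nm)$codes,
                      error = function(e) character(0))
    noop <- !is.null(config) && length(codes) > 0 &&
      all(vapply(codes, is_baseline_noop, logical(1L), config = config))
    if (noop) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = nm, n = s0$n, median = s0$median, q25 = s0$q25,
        q75 = s0$q75, p90 = s0$p90, mwu_p = NA_real_,
        median_reduction_pct = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, note = "Current baseline")
      next
    }
    s <- pooled_summary(ex)
    cmp <- percent_reduction_ci(baseline, ex, n_boot = n_boot, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = nm, n = s$n, median = s$median, q25 = s$q25, q75 = s$q75,
      p90 = s$p90, mwu_p = cmp$mwu_p,
      median_reduction_pct = cmp$median_reduction_pct,
      ci_low = cmp$ci95["median", "low"],
      ci_high = cmp$ci95["median", "high"], note = "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Round minute-valued columns for serialized outputs (quantiles are computed
# on full precision before rounding).
.round_minutes <- function(df, cols, digits = 3) {
  for (cl in intersect(cols, names(df))) df[[cl]] <- round(df[[cl]], digits)
  df
}

#' Export patient records as CSV
#'
#' @param experiment A `dnt_experiment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(experiment, path) {
  stopifnot(inherits(experiment, "dnt_experiment"))
  rec <- .round_minutes(experiment$records,
                        c("door_minute", "needle_minute", "dnt_minutes"))
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a result file byte-identically:
#' the full configuration content, scenario, replication count, horizon,
#' seed and package version.
#'
#' @param path Output JSON path.
#' @param config The [site_config()] used.
#' @param scenario Scenario label string.
#' @param n_reps,horizon_days,seed Run parameters.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, scenario, n_reps, horizon_days,
                           seed) {
  manifest <- list(
    package = "dntsim",
    version = as.character(utils::packageVersion("dntsim")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    scenario = scenario,
    n_reps = n_reps,
    horizon_days = horizon_days,
    seed = seed,
    config = config_to_list(config))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
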