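# Outcome measures and statistical machinery: pooled DNT summaries,
# percentage reductions with bootstrap confidence intervals, Mann-Whitney
# and chi-square verification tests, replication-count analysis, and
# one-at-a-time sensitivity sweeps.

.dnt_values <- function(x) {
  if (inherits(x, "dnt_experiment")) x$records$dnt_minutes
  else if (is.data.frame(x)) x$dnt_minutes
  else as.numeric(x)
}

.dnt_by_rep <- function(x) {
  rec <- if (inherits(x, "dnt_experiment")) x$records else x
  if (!is.data.frame(rec) || is.null(rec$replication_id)) {
    stop("need patient records with a replication_id column")
  }
  split(rec$dnt_minutes, rec$replication_id)
}

#' Pooled DNT summary statistics
#'
#' Summarises door-to-needle times pooled over all replications: patient
#' count, median, interquartile range endpoints, and the 90th percentile.
#' Quantiles are computed on the concatenated sample (not averaged across
#' replications) with the linear-interpolation definition
#' (`stats::quantile()` type 7).
#'
#' @param x A `dnt_experiment`, a patient-record data frame, or a numeric
#'   vector of DNTs in minutes.
#' @return An object of class `dnt_summary`: list with `n`, `median`,
#'   `q25`, `q75`, `p90`.
#' @export
pooled_summary <- function(x) {
  v <- .dnt_values(x)
  if (!length(v)) stop("no patient records to summarise")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  structure(list(n = length(v), median = q[2], q25 = q[1], q75 = q[3],
                 p90 = q[4]),
            class = "dnt_summary")
}

#' @export
print.dnt_summary <- function(x, ...) {
  cat(sprintf("n = %d | median DNT %.1f (IQR %.1f-%.1f) | P90 %.1f min\n",
              x$n, x$median, x$q25, x$q75, x$p90))
  invisible(x)
}

.reduction_metrics <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1], p90 = q[4])
}

#' Percentage DNT reduction with bootstrap confidence intervals
#'
#' Compares a scenario experiment against its baseline. Point estimates are
#' `100 * (baseline - scenario) / baseline` on the pooled median, IQR width,
#' and 90th percentile. Confidence intervals come from a percentile
#' bootstrap that resamples replications with replacement and recomputes the
#' pooled metrics each draw; when the two arms have the same number of
#' replications the resampling is paired (the arms share arrival streams
#' under common random numbers), otherwise independent. Also reports the
#' two-sided Mann-Whitney p-value on the pooled DNT samples.
#'
#' @param baseline,scenario `dnt_experiment` objects (or patient-record data
#'   frames with `replication_id` and `dnt_minutes` columns).
#' @param n_boot Number of bootstrap draws (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed making the bootstrap reproducible.
#' @return An object of class `dnt_comparison`: reduction point estimates
#'   (percent), a `ci` matrix with `low`/`high` per metric, and `mwu`.
#' @export
percent_reduction_ci <- function(baseline, scenario, n_boot = 10000,
                                 conf = 0.95, seed = NULL) {
  base_reps <- .dnt_by_rep(baseline)
  scen_reps <- .dnt_by_rep(scenario)
  if (length(base_reps) < 2L || length(scen_reps) < 2L) {
    stop("need at least 2 replications in each arm")
  }
  m_base <- .reduction_metrics(unlist(base_reps, use.names = FALSE))
  m_scen <- .reduction_metrics(unlist(scen_reps, use.names = FALSE))
  if (m_base[["median"]] == 0) {
    stop("baseline metric is zero; percentage reduction undefined")
  }
  point <- ifelse(m_base == 0, NA_real_, 100 * (m_base - m_scen) / m_base)
  names(point) <- names(m_base)

  if (!is.null(seed)) set.seed(seed)
  paired <- length(base_reps) == length(scen_reps)
  nb <- length(base_reps); ns <- length(scen_reps)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 3L)
  for (b in seq_len(n_boot)) {
    ib <- sample.int(nb, nb, replace = TRUE)
    is <- if (paired) ib else sample.int(ns, ns, replace = TRUE)
    mb <- .reduction_metrics(unlist(base_reps[ib], use.names = FALSE))
    ms <- .reduction_metrics(unlist(scen_reps[is], use.names = FALSE))
    draws[b, ] <- ifelse(mb == 0, NA_real_, 100 * (mb - ms) / mb)
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(draws, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(c(NA_real_, NA_real_))
    stats::quantile(col, probs = c(alpha, 1 - alpha), names = FALSE)
  }))
  dimnames(ci) <- list(c("median", "iqr", "p90"), c("low", "high"))

  mwu <- mann_whitney_u(unlist(base_reps, use.names = FALSE),
                        unlist(scen_reps, use.names = FALSE))
  structure(list(median_reduction_pct = unname(point["median"]),
                 iqr_reduction_pct = unname(point["iqr"]),
                 p90_reduction_pct = unname(point["p90"]),
                 ci95 = ci, conf = conf, n_boot = n_boot,
                 paired_bootstrap = paired,
                 mwu_p = mwu$p.value, mwu_U = mwu$statistic),
            class = "dnt_comparison")
}

#' @export
print.dnt_comparison <- function(x, ...) {
  cat(sprintf(
    "DNT reduction: median %.1f%% (%.0f%% CI %.1f-%.1f) | IQR %.1f%% | P90 %.1f%%\n",
    x$median_reduction_pct, 100 * x$conf, x$ci95["median", "low"],
    x$ci95["median", "high"], x$iqr_reduction_pct, x$p90_reduction_pct))
  cat(sprintf("Mann-Whitney U = %.1f, two-sided p = %.4g\n", x$mwu_U, x$mwu_p))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples: exact enumeration when both
#' samples have at most eight observations and there are no ties, otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `statistic` (U for the first sample) and `p.value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) <= 8L && length(y) <= 8L && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Chi-square goodness-of-fit test
#'
#' Pearson statistic `sum((O - E)^2 / E)` against user-supplied expected
#' counts, with a chi-square reference on `k - 1` degrees of freedom. Used
#' to verify simulated arrival-block counts against the desired volumes.
#'
#' @param observed Observed counts (length >= 2).
#' @param expected Expected counts, all positive, same length.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
chi_square_gof <- function(observed, expected) {
  observed <- as.numeric(observed)
  expected <- as.numeric(expected)
  if (length(observed) != length(expected)) {
    stop("observed and expected must have equal length")
  }
  if (length(observed) < 2L) stop("need at least two categories")
  if (any(!is.finite(expected)) || any(expected <= 0)) {
    stop("expected counts must all be positive")
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Replications needed for a target precision
#'
#' Standard sequential replication-count analysis: from a pilot sample of
#' per-replication outcomes, the smallest number of replications `n` whose
#' t-based confidence half-width `t(1 - alpha/2, n - 1) * s / sqrt(n)` is at
#' most `relative_precision` times the pilot mean.
#'
#' @param pilot Numeric vector of per-replication outcome values (>= 2).
#' @param relative_precision Target half-width as a fraction of the mean
#'   (default 0.05).
#' @param confidence Confidence level (default 0.95).
#' @return Smallest sufficient replication count (minimum 2).
#' @export
replications_needed <- function(pilot, relative_precision = 0.05,
                                confidence = 0.95) {
  if (length(pilot) < 2L) stop("need at least 2 pilot replications")
  m <- mean(pilot)
  if (m == 0) stop("pilot mean is zero; relative precision undefined")
  s <- stats::sd(pilot)
  target <- relative_precision * abs(m)
  for (n in 2:1e6) {
    hw <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * s / sqrt(n)
    if (hw <= target) return(n)
  }
  stop("no replication count below 1e6 achieves the requested precision")
}

#' One-at-a-time sensitivity sweep
#'
#' Re-runs an experiment with a single activity role's duration
#' distributions scaled by a factor, one grid point at a time, under common
#' random numbers (every run reuses the same seeds, so a factor of 1
#' reproduces the unperturbed summary exactly).
#'
#' @param config A valid [site_config()].
#' @param grid Data frame with columns `role` and `factor`.
#' @param scenario Optional scenario applied before perturbing.
#' @param n_reps,horizon_days,base_seed Passed to [run_experiment()].
#' @return Data frame: one row per grid point with the pooled summary
#'   (`n`, `median`, `q25`, `q75`, `p90`).
#' @export
sensitivity_sweep <- function(config, grid, scenario = NULL, n_reps = 30,
                              horizon_days = 365, base_seed = 1L) {
  if (!is.data.frame(grid) || !all(c("role", "factor") %in% names(grid))) {
    stop("grid must be a data frame with columns 'role' and 'factor'")
  }
  if (!is.null(scenario)) {
    config <- apply_scenarios(config, as_scenario_spec(scenario))
  }
  assert_valid_config(config)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    role <- as.character(grid$role[i])
    factor <- as.numeric(grid$factor[i])
    ids <- role_ids(config, role)
    if (!length(ids)) stop("unknown activity role in grid: ", role)
    cfg <- config
    for (id in ids) cfg <- .scale_activity_dists(cfg, id, factor)
    s <- pooled_summary(run_experiment(cfg, NULL, n_reps = n_reps,
                                       horizon_days = horizon_days,
                                       base_seed = base_seed))
    data.frame(role = role, factor = factor, n = s$n, median = s$median,
               q25 = s$q25, q75 = s$q75, p90 = s$p90)
  })
  do.call(rbind, rows)
}
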