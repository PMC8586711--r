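# Non-homogeneous patient arrival generation and hours classification.
#
# Arrivals follow a piecewise-constant-rate Poisson process over twelve
# two-hour clock blocks (00-02, 02-04, ..., 22-24), identical across days of
# the week. The weekly regular/out-of-hours split (Mon-Fri 08:00-16:00)
# therefore emerges purely from the time-of-day profile times 5/7.

#' Define an arrival-rate schedule
#'
#' @param block_rates Twelve non-negative hourly arrival rates, one per
#'   two-hour clock block starting at midnight.
#' @param scale Positive site-level multiplier on all rates (smaller
#'   hospitals see proportionally fewer strokes).
#' @return An object of class `arrival_schedule`.
#' @examples
#' sched <- arrival_schedule(site1_block_rates())
#' expected_regular_fraction(sched)
#' @export
arrival_schedule <- function(block_rates, scale = 1) {
  block_rates <- as.numeric(block_rates)
  if (length(block_rates) != 12L || anyNA(block_rates) ||
      any(block_rates < 0)) {
    stop("block_rates must be 12 non-negative hourly rates")
  }
  if (!any(block_rates > 0)) {
    stop("at least one block rate must be positive")
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("scale must be a single positive number")
  }
  structure(list(block_rates = block_rates, scale = scale),
            class = "arrival_schedule")
}

#' @describeIn arrival_schedule The urban reference site's hourly arrival
#'   rates per two-hour block, estimated from one year of stroke arrivals.
#' @export
site1_block_rates <- function() {
  c(0.00428, 0.00321, 0.00321, 0.00642, 0.01391, 0.01819,
    0.01926, 0.01712, 0.01712, 0.01605, 0.01070, 0.00856)
}

MINUTES_PER_DAY <- 1440
MINUTES_PER_WEEK <- 10080

#' Generate patient arrival times
#'
#' Simulates the piecewise-constant-rate Poisson process over a horizon that
#' starts at Monday 00:00: within each two-hour block the arrival count is
#' Poisson with mean `rate * 2 * scale` and the times are uniform in the
#' block. Uses the current R RNG state; call `set.seed()` for reproducible
#' streams.
#'
#' @param schedule An [arrival_schedule()].
#' @param horizon_days Number of simulated days (default 365; no leap
#'   handling).
#' @return Sorted numeric vector of arrival times in minutes from horizon
#'   start, all within `[0, horizon)`.
#' @export
generate_arrivals <- function(schedule, horizon_days = 365) {
  stopifnot(inherits(schedule, "arrival_schedule"))
  if (!is.numeric(horizon_days) || horizon_days < 1) {
    stop("horizon_days must be >= 1")
  }
  n_blocks <- as.integer(horizon_days) * 12L
  rates <- rep(schedule$block_rates, length.out = n_blocks)
  counts <- stats::rpois(n_blocks, lambda = rates * 2 * schedule$scale)
  if (sum(counts) == 0L) return(numeric(0))
  block_start <- rep((seq_len(n_blocks) - 1L) * 120, counts)
  sort(block_start + stats::runif(sum(counts)) * 120)
}

#' Classify a time as regular or out-of-hours
#'
#' Regular hours are Monday-Friday 08:00-16:00 (half-open: 16:00 itself is
#' out of hours); everything else, including all weekend times, is
#' out-of-hours. Time 0 is Monday 00:00.
#'
#' @param t Minutes from horizon start (Monday 00:00); non-negative.
#' @return Character vector of `"regular"` / `"out"`.
#' @export
classify_hours <- function(t) {
  if (any(t < 0)) stop("time must be non-negative")
  week_min <- t %% MINUTES_PER_WEEK
  day <- floor(week_min / MINUTES_PER_DAY)        # 0 = Monday
  tod <- week_min %% MINUTES_PER_DAY
  ifelse(day <= 4 & tod >= 480 & tod < 960, "regular", "out")
}

#' Assign arrival pathways
#'
#' Independent Bernoulli draws: each patient arrives by ambulance (EMS) with
#' probability `p_ems`, otherwise by private vehicle (PV).
#'
#' @param n Number of patients.
#' @param p_ems EMS probability in `[0, 1]` (default 0.80).
#' @return Character vector of `"EMS"` / `"PV"`.
#' @export
assign_pathway <- function(n, p_ems = 0.80) {
  if (p_ems < 0 || p_ems > 1) stop("p_ems must be in [0, 1]")
  ifelse(stats::runif(n) < p_ems, "EMS", "PV")
}

#' Analytic regular-hours arrival fraction
#'
#' The expected fraction of arrivals falling in Monday-Friday 08:00-16:00:
#' the schedule's 08-16 block proportions (rates normalised to sum one)
#' times 5/7, since rates are identical across days of the week.
#'
#' @param schedule An [arrival_schedule()].
#' @return Fraction in `[0, 1]`.
#' @export
expected_regular_fraction <- function(schedule) {
  stopifnot(inherits(schedule, "arrival_schedule"))
  r <- schedule$block_rates
  if (sum(r) == 0) stop("schedule has no positive rates")
  sum(r[5:8]) / sum(r) * 5 / 7
}

#' Expected arrival counts per block
#'
#' @param schedule An [arrival_schedule()].
#' @param horizon_days Days per replication.
#' @param n_reps Number of replications pooled.
#' @return Numeric vector of 12 expected counts, one per two-hour block.
#' @export
expected_block_counts <- function(schedule, horizon_days = 365,
                                  n_reps = 30) {
  stopifnot(inherits(schedule, "arrival_schedule"))
  schedule$block_rates * 2 * schedule$scale * horizon_days * n_reps
}

#' @export
print.arrival_schedule <- function(x, ...) {
  cat("<arrival_schedule>\n  hourly rates by 2-h block:\n")
  labs <- sprintf("%02d-%02d", seq(0, 22, 2), seq(2, 24, 2))
  cat(paste0("    ", labs, ": ", format(x$block_rates, digits = 3),
             collapse = "\n"), "\n")
  cat(sprintf("  scale: %.4f | expected arrivals/year: %.1f\n",
              x$scale, sum(x$block_rates) * 2 * x$scale * 365))
  cat(sprintf("  expected regular-hours fraction: %.1f%%\n",
              100 * expected_regular_fraction(x)))
  invisible(x)
}
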