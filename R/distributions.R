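# Parametric duration distributions for activity times, in minutes.
#
# All sampling goes through inverse-CDF transforms of uniforms drawn from the
# R RNG. This gives two properties the simulator depends on:
#   * seed determinism: equal (distribution, seed) -> identical draw streams;
#   * exact scale equivariance: scaling a distribution by k maps each draw u
#     to k * q(u), so a scaled distribution reproduces factor-times-original
#     samples under common random numbers.
# A positive lower bound is handled by inverting the truncated CDF, which is
# equal in law to resampling until the draw clears the bound but keeps the
# one-uniform-per-draw bookkeeping exact (and puts no point mass at the bound).

.DIST_FAMILIES <- c("constant", "uniform", "triangular", "exponential",
                    "lognormal", "truncnorm", "empirical")

#' Construct a duration distribution
#'
#' A `duration_dist` is a parametric law for an activity duration in minutes.
#' Seven families are supported: `constant`, `uniform`, `triangular`,
#' `exponential` (parameterised by its mean), `lognormal` (`meanlog`,
#' `sdlog`), `truncnorm` (normal with `mean`, `sd`, truncated at
#' `lower_bound`), and `empirical` (a finite set of atoms sampled uniformly).
#' Samples are always finite and at least `lower_bound` (default 0): families
#' with unbounded-below support are truncated by inverse-CDF conditioning.
#'
#' @param family One of `"constant"`, `"uniform"`, `"triangular"`,
#'   `"exponential"`, `"lognormal"`, `"truncnorm"`, `"empirical"`.
#' @param params Named numeric vector (or list) of family parameters:
#'   `value`; `min`, `max`; `min`, `mode`, `max`; `mean`; `meanlog`, `sdlog`;
#'   `mean`, `sd`; or, for `empirical`, a numeric vector of atoms.
#' @param lower_bound Minimum attainable duration in minutes (default 0).
#' @param provenance Free-text origin tag carried through serialization,
#'   e.g. `"calibrated"` for shipped stand-ins or `"SM1"` for transcribed
#'   source tables.
#' @return An object of class `duration_dist`.
#' @examples
#' d <- duration_dist("triangular", c(min = 5, mode = 10, max = 15))
#' dist_median(d)
#' set.seed(1); sample_duration(d, 3)
#' @export
duration_dist <- function(family, params, lower_bound = 0,
                          provenance = "unspecified") {
  family <- match.arg(family, .DIST_FAMILIES)
  if (!is.numeric(lower_bound) || length(lower_bound) != 1L ||
      !is.finite(lower_bound) || lower_bound < 0) {
    stop("lower_bound must be a single finite non-negative number")
  }
  if (family == "empirical") {
    atoms <- as.numeric(unlist(params, use.names = FALSE))
    if (length(atoms) < 1L || anyNA(atoms) || any(!is.finite(atoms))) {
      stop("empirical distribution needs at least one finite atom")
    }
    if (any(atoms < lower_bound)) {
      stop("empirical atoms must all be >= lower_bound")
    }
    params <- list(atoms = sort(atoms))
  } else {
    params <- as.list(params)
    if (is.null(names(params)) || any(!nzchar(names(params)))) {
      stop("params must be named for family '", family, "'")
    }
    need <- switch(family,
      constant    = "value",
      uniform     = c("min", "max"),
      triangular  = c("min", "mode", "max"),
      exponential = "mean",
      lognormal   = c("meanlog", "sdlog"),
      truncnorm   = c("mean", "sd")
    )
    missing <- setdiff(need, names(params))
    if (length(missing)) {
      stop("family '", family, "' requires parameter(s): ",
           paste(missing, collapse = ", "))
    }
    params <- lapply(params[need], as.numeric)
    if (any(vapply(params, function(p) length(p) != 1L || !is.finite(p),
                   logical(1L)))) {
      stop("parameters for family '", family, "' must be single finite values")
    }
    switch(family,
      constant = if (params$value < lower_bound)
        stop("constant value must be >= lower_bound"),
      uniform = {
        if (params$min > params$max) stop("uniform requires min <= max")
        if (params$min < lower_bound) stop("uniform min must be >= lower_bound")
      },
      triangular = {
        if (!(params$min <= params$mode && params$mode <= params$max)) {
          stop("triangular requires min <= mode <= max")
        }
        if (params$min < lower_bound)
          stop("triangular min must be >= lower_bound")
      },
      exponential = if (params$mean <= 0)
        stop("exponential mean must be > 0"),
      lognormal = if (params$sdlog < 0)
        stop("lognormal sdlog must be >= 0"),
      truncnorm = if (params$sd <= 0)
        stop("truncnorm sd must be > 0")
    )
  }
  structure(
    list(family = family, params = params, lower_bound = lower_bound,
         provenance = provenance),
    class = "duration_dist"
  )
}

#' @rdname duration_dist
#' @param value,min,mode,max,mean,meanlog,sdlog,sd,atoms Family parameters in
#'   minutes (log-minutes for `meanlog`/`sdlog`).
#' @param ... Passed on to [duration_dist()].
#' @export
dist_constant <- function(value, ...) {
  duration_dist("constant", c(value = value), ...)
}

#' @rdname duration_dist
#' @export
dist_uniform <- function(min, max, ...) {
  duration_dist("uniform", c(min = min, max = max), ...)
}

#' @rdname duration_dist
#' @export
dist_triangular <- function(min, mode, max, ...) {
  duration_dist("triangular", c(min = min, mode = mode, max = max), ...)
}

#' @rdname duration_dist
#' @export
dist_exponential <- function(mean, ...) {
  duration_dist("exponential", c(mean = mean), ...)
}

#' @rdname duration_dist
#' @export
dist_lognormal <- function(meanlog, sdlog, ...) {
  duration_dist("lognormal", c(meanlog = meanlog, sdlog = sdlog), ...)
}

#' @rdname duration_dist
#' @export
dist_truncnorm <- function(mean, sd, ...) {
  duration_dist("truncnorm", c(mean = mean, sd = sd), ...)
}

#' @rdname duration_dist
#' @export
dist_empirical <- function(atoms, ...) {
  duration_dist("empirical", atoms, ...)
}

is_duration_dist <- function(x) inherits(x, "duration_dist")

# Untruncated quantile function, vectorised over u in [0, 1].
.dist_quantile_raw <- function(dist, u) {
  p <- dist$params
  switch(dist$family,
    constant = rep(p$value, length(u)),
    uniform = p$min + u * (p$max - p$min),
    triangular = {
      a <- p$min; m <- p$mode; b <- p$max
      if (a == b) return(rep(a, length(u)))
      fm <- (m - a) / (b - a)
      lower <- u < fm
      out <- numeric(length(u))
      out[lower] <- a + sqrt(u[lower] * (b - a) * (m - a))
      out[!lower] <- b - sqrt((1 - u[!lower]) * (b - a) * (b - m))
      out
    },
    exponential = stats::qexp(u, rate = 1 / p$mean),
    lognormal = stats::qlnorm(u, meanlog = p$meanlog, sdlog = p$sdlog),
    truncnorm = stats::qnorm(u, mean = p$mean, sd = p$sd),
    empirical = {
      atoms <- p$atoms
      n <- length(atoms)
      atoms[pmin(n, floor(u * n) + 1L)]
    }
  )
}

# Untruncated CDF at a single point (used to condition on the lower bound).
.dist_cdf_raw <- function(dist, x) {
  p <- dist$params
  switch(dist$family,
    constant = as.numeric(x >= p$value),
    uniform = {
      if (p$max == p$min) as.numeric(x >= p$min)
      else min(1, max(0, (x - p$min) / (p$max - p$min)))
    },
    triangular = {
      a <- p$min; m <- p$mode; b <- p$max
      if (a == b) return(as.numeric(x >= a))
      if (x <= a) 0
      else if (x >= b) 1
      else if (x <= m) (x - a)^2 / ((b - a) * (m - a))
      else 1 - (b - x)^2 / ((b - a) * (b - m))
    },
    exponential = stats::pexp(x, rate = 1 / p$mean),
    lognormal = stats::plnorm(x, meanlog = p$meanlog, sdlog = p$sdlog),
    truncnorm = stats::pnorm(x, mean = p$mean, sd = p$sd),
    empirical = mean(p$atoms <= x)
  )
}

#' Quantiles of a duration distribution
#'
#' Closed-form quantile function honouring the lower bound (the law is the
#' family law conditioned on exceeding `lower_bound`).
#'
#' @param dist A [duration_dist()].
#' @param p Probabilities in `[0, 1]`.
#' @return Durations in minutes, same length as `p`.
#' @export
dist_quantile <- function(dist, p) {
  stopifnot(is_duration_dist(dist))
  if (any(p < 0 | p > 1)) stop("quantile probabilities must be in [0, 1]")
  f0 <- .dist_cdf_raw(dist, dist$lower_bound)
  if (f0 > 0 && dist$family %in% c("exponential", "lognormal", "truncnorm")) {
    p <- f0 + p * (1 - f0)
  }
  pmax(.dist_quantile_raw(dist, p), dist$lower_bound)
}

#' @describeIn dist_quantile Closed-form median (the 0.5 quantile; for
#'   `empirical`, the sample median of the atoms).
#' @export
dist_median <- function(dist) {
  stopifnot(is_duration_dist(dist))
  if (dist$family == "empirical") {
    return(stats::median(dist$params$atoms))
  }
  dist_quantile(dist, 0.5)
}

#' Sample activity durations
#'
#' Draws `n` durations by inverse-CDF transform of `stats::runif()` uniforms,
#' so the stream is reproducible under `set.seed()` and scaled distributions
#' yield exactly factor-times-original draws under the same seed.
#'
#' @param dist A [duration_dist()].
#' @param n Number of draws.
#' @return Numeric vector of durations in minutes, all `>= dist$lower_bound`.
#' @export
sample_duration <- function(dist, n = 1L) {
  stopifnot(is_duration_dist(dist))
  if (!is.numeric(n) || n < 0) stop("n must be a non-negative count")
  dist_quantile(dist, stats::runif(n))
}

#' Scale a duration distribution
#'
#' Returns the distribution of `factor` times the original duration; under
#' the same seed its samples are exactly `factor` times the original samples.
#' Used by the 35%-reduction scenarios (`factor = 0.65`) and by global
#' calibration. The lower bound scales too.
#'
#' @param dist A [duration_dist()].
#' @param factor Positive multiplier.
#' @return A new `duration_dist`.
#' @export
scale_dist <- function(dist, factor) {
  stopifnot(is_duration_dist(dist))
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("scale factor must be a single positive number")
  }
  if (factor == 1) return(dist)
  p <- dist$params
  params <- switch(dist$family,
    constant    = c(value = p$value * factor),
    uniform     = c(min = p$min * factor, max = p$max * factor),
    triangular  = c(min = p$min * factor, mode = p$mode * factor,
                    max = p$max * factor),
    exponential = c(mean = p$mean * factor),
    lognormal   = c(meanlog = p$meanlog + log(factor), sdlog = p$sdlog),
    truncnorm   = c(mean = p$mean * factor, sd = p$sd * factor),
    empirical   = p$atoms * factor
  )
  duration_dist(dist$family, params, lower_bound = dist$lower_bound * factor,
                provenance = dist$provenance)
}

#' @export
print.duration_dist <- function(x, ...) {
  pstr <- if (x$family == "empirical") {
    sprintf("%d atoms in [%.3g, %.3g]", length(x$params$atoms),
            min(x$params$atoms), max(x$params$atoms))
  } else {
    paste(sprintf("%s=%.4g", names(x$params), unlist(x$params)),
          collapse = ", ")
  }
  cat(sprintf("<duration_dist %s(%s)%s, median %.2f min [%s]>\n",
              x$family, pstr,
              if (x$lower_bound > 0)
                sprintf(", lower_bound=%.3g", x$lower_bound) else "",
              dist_median(x), x$provenance))
  invisible(x)
}

#' @export
format.duration_dist <- function(x, ...) {
  if (x$family == "empirical") {
    sprintf("empirical(%d atoms)", length(x$params$atoms))
  } else {
    sprintf("%s(%s)", x$family,
            paste(sprintf("%.4g", unlist(x$params)), collapse = ", "))
  }
}
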