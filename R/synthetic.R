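#' Specification of a synthetic PM2.5-like hourly series
#'
#' The generator emulates the summary traits of urban hourly PM2.5 records:
#' strictly positive values, mean greater than the median, positive skew,
#' kurtosis above 6 and roughly 3% of values above the upper IQR fence. It
#' uses a log-additive model: `log(value) = log(base_median) + diurnal term
#' (24 h period) + seasonal term (1 y period) + Gaussian noise`, with a
#' Bernoulli multiplicative contamination producing the upper outliers.
#'
#' @param n_years number of calendar years to generate (>= 1).
#' @param start_year first calendar year (leap days are generated and are
#'   meant to be removed by [clean_series()]).
#' @param base_median baseline median concentration in \eqn{\mu g/m^3}
#'   (default 14, the magnitude observed at urban background stations).
#' @param diurnal_amplitude log-scale amplitude of the 24 h cycle
#'   (default 0.35, a ~40% swing around the daily mean).
#' @param seasonal_amplitude log-scale amplitude of the annual cycle
#'   (default 0.15).
#' @param tail_sigma log-scale standard deviation of the hourly noise
#'   (default 0.45; together with the contamination this yields the
#'   heavy-tailed marginal).
#' @param outlier_rate fraction of hours hit by the multiplicative
#'   contamination (default 0.03).
#' @param outlier_scale multiplier applied to contaminated hours (default 3).
#' @param seed integer seed of the generation stream.
#' @return object of class `series_spec`.
#' @export
series_spec <- function(n_years = 1L, start_year = 2019L, base_median = 14,
                        diurnal_amplitude = 0.35, seasonal_amplitude = 0.15,
                        tail_sigma = 0.45, outlier_rate = 0.03,
                        outlier_scale = 3, seed = 1L) {
  spec <- list(n_years = as.integer(n_years),
               start_year = as.integer(start_year),
               base_median = base_median,
               diurnal_amplitude = diurnal_amplitude,
               seasonal_amplitude = seasonal_amplitude,
               tail_sigma = tail_sigma, outlier_rate = outlier_rate,
               outlier_scale = outlier_scale, seed = as.integer(seed))
  if (spec$n_years < 1L) stop("`n_years` must be >= 1", call. = FALSE)
  if (spec$base_median <= 0) stop("`base_median` must be > 0", call. = FALSE)
  if (spec$tail_sigma < 0) stop("`tail_sigma` must be >= 0", call. = FALSE)
  if (spec$outlier_rate < 0 || spec$outlier_rate > 1)
    stop("`outlier_rate` must lie in [0, 1]", call. = FALSE)
  if (spec$diurnal_amplitude < 0 || spec$seasonal_amplitude < 0)
    stop("amplitudes must be >= 0", call. = FALSE)
  if (spec$outlier_scale <= 0) stop("`outlier_scale` must be > 0",
                                    call. = FALSE)
  structure(spec, class = "series_spec")
}

#' Specification of injected missingness
#'
#' Describes the two mechanisms observed in hourly monitoring records:
#' isolated MCAR hours, and NMAR runs of consecutive missing hours caused by
#' sensor outages. Runs never overlap and never touch another masked slot, so
#' each placed run is recovered as one maximal gap run of exactly the drawn
#' length.
#'
#' @param mcar_rate fraction of hours masked in isolation, in \[0, 1).
#' @param run_count number of NMAR runs to place.
#' @param run_lengths run-length law: an integer vector (recycled to
#'   `run_count`; all >= 2) or a function `f(n)` returning `n` integer
#'   lengths.
#' @param seed integer seed of the masking stream (independent of the
#'   generation stream so patterns can vary on a fixed series).
#' @return object of class `missingness_spec`.
#' @export
missingness_spec <- function(mcar_rate = 0.01, run_count = 0L,
                             run_lengths = integer(0), seed = 1L) {
  if (mcar_rate < 0 || mcar_rate >= 1)
    stop("`mcar_rate` must lie in [0, 1)", call. = FALSE)
  run_count <- as.integer(run_count)
  if (run_count < 0L) stop("`run_count` must be >= 0", call. = FALSE)
  if (!is.function(run_lengths)) {
    run_lengths <- as.integer(run_lengths)
    if (run_count > 0L) {
      if (length(run_lengths) == 0L)
        stop("supply `run_lengths` when `run_count` > 0", call. = FALSE)
      if (any(run_lengths < 2L))
        stop("run lengths must be >= 2", call. = FALSE)
    }
  }
  structure(list(mcar_rate = mcar_rate, run_count = run_count,
                 run_lengths = run_lengths, seed = as.integer(seed)),
            class = "missingness_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic heavy-tailed hourly series
#'
#' Fully reproducible from `spec$seed`; the same spec always yields the same
#' series. Values are strictly positive by construction (lognormal model).
#' The grid follows the real calendar, including 29 February in leap years,
#' so [clean_series()] behaves exactly as on observed data.
#'
#' @param spec a [series_spec()].
#' @return an [hourly_series()].
#' @export
generate_hourly_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  start <- as.POSIXct(sprintf("%d-01-01 00:00:00", spec$start_year),
                      tz = "UTC")
  end <- as.POSIXct(sprintf("%d-12-31 23:00:00",
                            spec$start_year + spec$n_years - 1L), tz = "UTC")
  time <- seq(start, end, by = "hour")
  n <- length(time)
  lt <- as.POSIXlt(time)
  hour <- lt$hour
  doy <- lt$yday
  logv <- with_seed(spec$seed, {
    base <- log(spec$base_median) +
      spec$diurnal_amplitude * cos(2 * pi * (hour - 8) / 24) +
      spec$seasonal_amplitude * sin(2 * pi * doy / 365) +
      stats::rnorm(n, 0, spec$tail_sigma)
    hit <- stats::runif(n) < spec$outlier_rate
    base + ifelse(hit, log(spec$outlier_scale), 0)
  })
  hourly_series(exp(logv), time = time)
}

#' Mask a fully valid series with MCAR hours and NMAR runs
#'
#' NMAR runs are placed first, uniformly among feasible non-overlapping
#' starts (rejection sampling, at most 1000 attempts per run, each run kept
#' clear of other masked slots by a one-slot buffer so gap runs stay
#' maximal). Isolated MCAR hours are then drawn at `mcar_rate`, skipping
#' slots adjacent to already-masked ones.
#'
#' @param series a fully valid [hourly_series()].
#' @param mspec a [missingness_spec()].
#' @return list with `series` (the masked [hourly_series()]) and `truth`
#'   (numeric vector of the removed true values, named by slot position).
#' @export
inject_missingness <- function(series, mspec) {
  stopifnot(inherits(series, "hourly_series"),
            inherits(mspec, "missingness_spec"))
  if (!all(series$valid))
    stop("`series` must be fully valid before masking", call. = FALSE)
  n <- length(series)
  masked <- logical(n)
  with_seed(mspec$seed, {
    if (mspec$run_count > 0L) {
      lens <- if (is.function(mspec$run_lengths))
        as.integer(mspec$run_lengths(mspec$run_count))
      else rep_len(mspec$run_lengths, mspec$run_count)
      if (any(lens < 2L)) stop("run lengths must be >= 2", call. = FALSE)
      for (len in lens) {
        placed <- FALSE
        for (attempt in seq_len(1000L)) {
          s <- sample.int(n - len + 1L, 1L)
          span <- max(1L, s - 1L):min(n, s + len)
          if (!any(masked[span])) {
            masked[s:(s + len - 1L)] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place a run of length ", len,
               " without overlap after 1000 attempts", call. = FALSE)
      }
    }
    if (mspec$mcar_rate > 0) {
      cand <- which(stats::runif(n) < mspec$mcar_rate)
      for (p in sample(cand)) {
        span <- max(1L, p - 1L):min(n, p + 1L)
        if (!any(masked[span])) masked[p] <- TRUE
      }
    }
  })
  pos <- which(masked)
  truth <- series$value[pos]
  names(truth) <- pos
  out <- series
  out$valid[pos] <- FALSE
  out$value[pos] <- NA_real_
  list(series = out, truth = truth)
}

#' Transfer a missingness template onto a complete series
#'
#' Masks exactly the given positions, mimicking the transfer of one month's
#' observed missingness pattern onto a complete reference month when
#' validating imputation methods.
#'
#' @param base an [hourly_series()], valid at every template position.
#' @param template_positions integer positions to mask.
#' @return list with `series` and `truth` as in [inject_missingness()].
#' @export
make_validation_case <- function(base, template_positions) {
  stopifnot(inherits(base, "hourly_series"))
  pos <- sort(unique(as.integer(template_positions)))
  if (length(pos) && (min(pos) < 1L || max(pos) > length(base)))
    stop("template positions outside the base series", call. = FALSE)
  if (!all(base$valid[pos]))
    stop("template positions must be valid in `base`", call. = FALSE)
  truth <- base$value[pos]
  names(truth) <- pos
  out <- base
  out$valid[pos] <- FALSE
  out$value[pos] <- NA_real_
  list(series = out, truth = truth)
}
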