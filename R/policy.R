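#' Run-length imputation policy
#'
#' The policy routes each maximal gap run to a method by its length L, using
#' half-open brackets at the thresholds 20/40/70 (a boundary length goes to
#' the higher bracket): L < 20 piecewise linear interpolation; 20 <= L < 40
#' the Set-3 median MeD ("one day with a three-hour frame for five years");
#' 40 <= L < 70 the Set-7 median Me5 (same date and hour in the five prior
#' years); L >= 70 the Set-3 mean MeanD. Units (years) listed in
#' `excluded_units` are never imputed, mirroring the decision to leave the
#' comparison year untouched.
#'
#' @param t1,t2,t3 run-length thresholds, `t1 < t2 < t3` (defaults 20, 40,
#'   70).
#' @param short_method interpolation method name for short runs (default
#'   `"piecewise_linear"`).
#' @param mid_method,long_method,very_long_method lists `list(set =, estimator
#'   =)` naming a neighborhood set and a location estimator.
#' @param excluded_units integer years never imputed.
#' @return object of class `imputation_policy`.
#' @export
imputation_policy <- function(t1 = 20L, t2 = 40L, t3 = 70L,
                              short_method = "piecewise_linear",
                              mid_method = list(set = 3L,
                                                estimator = "median"),
                              long_method = list(set = 7L,
                                                 estimator = "median"),
                              very_long_method = list(set = 3L,
                                                      estimator = "mean"),
                              excluded_units = integer(0)) {
  t1 <- as.integer(t1); t2 <- as.integer(t2); t3 <- as.integer(t3)
  if (!(t1 < t2 && t2 < t3))
    stop("thresholds must satisfy t1 < t2 < t3", call. = FALSE)
  for (mm in list(mid_method, long_method, very_long_method)) {
    if (!is.list(mm) || !mm$set %in% 1:8 ||
        !mm$estimator %in% c("mean", "median", "trimmed_mean",
                             "andrews_wave"))
      stop("set/estimator methods must name a set 1..8 and a known estimator",
           call. = FALSE)
  }
  structure(list(t1 = t1, t2 = t2, t3 = t3, short_method = short_method,
                 mid_method = mid_method, long_method = long_method,
                 very_long_method = very_long_method,
                 excluded_units = as.integer(excluded_units)),
            class = "imputation_policy")
}

#' Read an imputation policy from a JSON file
#'
#' Expects fields `thresholds` (length-3 integer) and optional
#' `mid_method`/`long_method`/`very_long_method` (objects with `set` and
#' `estimator`) and `excluded_units`.
#'
#' @param path JSON file path.
#' @return an [imputation_policy()].
#' @export
read_policy_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("reading a policy file requires the jsonlite package",
         call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- imputation_policy()
  pick <- function(name) j[[name]] %||% defaults[[name]]
  th <- j$thresholds %||% c(defaults$t1, defaults$t2, defaults$t3)
  imputation_policy(t1 = th[1], t2 = th[2], t3 = th[3],
                    short_method = pick("short_method"),
                    mid_method = as.list(pick("mid_method")),
                    long_method = as.list(pick("long_method")),
                    very_long_method = as.list(pick("very_long_method")),
                    excluded_units = pick("excluded_units"))
}

policy_bracket <- function(policy, len) {
  if (len < policy$t1) "short"
  else if (len < policy$t2) "mid"
  else if (len < policy$t3) "long"
  else "very_long"
}

slot_estimate <- function(p, archive, method) {
  nb <- build_neighborhood(method$set, p, archive)
  need <- if (method$set == 8L) 2L else 1L
  if (length(nb$values) < need) {
    if (method$set %in% c(7L, 8L))
      return(general_estimate(p, archive))
    return(NA_real_)
  }
  robust_location(nb$values, method$estimator)
}

#' Impute a series with the run-length policy
#'
#' Each maximal gap run of `series` is routed by [imputation_policy()]. The
#' set-based methods compute one estimate per missing slot from the archive's
#' original valid values (never from values imputed in the same pass). Slots
#' whose neighborhood has no usable value are left missing and reported in a
#' warning.
#'
#' @param series the [hourly_series()] to fill; either the archive itself or
#'   a series whose time grid is a contiguous sub-span of the archive's.
#' @param archive a cleaned multi-year [hourly_series()] (defaults to
#'   `series`); must start on 1 January and span whole cleaned years.
#' @param policy an [imputation_policy()].
#' @return the imputed [hourly_series()] with `imputed` flags set.
#' @export
impute_with_policy <- function(series, archive = series,
                               policy = imputation_policy()) {
  stopifnot(inherits(series, "hourly_series"),
            inherits(policy, "imputation_policy"))
  assert_archive_grid(archive)
  offset <- 0L
  if (!identical(series, archive)) {
    offset <- match(as.numeric(series$time[1]), as.numeric(archive$time))
    if (is.na(offset) ||
        !all(as.numeric(series$time) ==
             as.numeric(archive$time[offset - 1L + seq_along(series$time)])))
      stop("`series` must be a contiguous sub-span of `archive`",
           call. = FALSE)
    offset <- offset - 1L
  }
  runs <- find_gap_runs(series)
  if (nrow(runs) == 0L) return(series)
  years <- series_calendar(series)$year
  out <- series
  unfilled <- integer(0)
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i]
    len <- runs$length[i]
    slots <- s:(s + len - 1L)
    if (any(years[slots] %in% policy$excluded_units)) next
    bracket <- policy_bracket(policy, len)
    if (bracket == "short") {
      seg <- interpolate_gaps(out, method = policy$short_method)
      out$value[slots] <- seg$value[slots]
      out$valid[slots] <- TRUE
      out$imputed[slots] <- TRUE
    } else {
      method <- policy[[paste0(bracket, "_method")]]
      for (p in slots) {
        est <- slot_estimate(p + offset, archive, method)
        if (is.na(est)) {
          unfilled <- c(unfilled, p)
        } else {
          out$value[p] <- est
          out$valid[p] <- TRUE
          out$imputed[p] <- TRUE
        }
      }
    }
  }
  if (length(unfilled))
    warning(length(unfilled), " slot(s) could not be imputed for lack of ",
            "archive coverage", call. = FALSE)
  out
}

#' Evaluate imputed values against withheld truth
#'
#' Computed only over the masked positions: Pearson's r, Kendall's tau
#' (tau-b, tie-corrected — hourly data ties are common), Spearman's rho
#' (ranks then Pearson) and the residual sum of squares.
#'
#' @param truth numeric vector of true values named by slot position (as
#'   returned by [inject_missingness()] or [make_validation_case()]).
#' @param imputed the imputed [hourly_series()]; every truth position must
#'   carry a value.
#' @return object of class `evaluation_result` with fields `pearson_r`,
#'   `kendall_tau`, `spearman_rho`, `rss`, `n_evaluated`.
#' @export
evaluate_imputation <- function(truth, imputed) {
  stopifnot(inherits(imputed, "hourly_series"))
  pos <- as.integer(names(truth))
  if (length(pos) != length(truth) || anyNA(pos))
    stop("`truth` must be named by integer slot positions", call. = FALSE)
  if (max(pos) > length(imputed))
    stop("truth positions outside the imputed series", call. = FALSE)
  est <- imputed$value[pos]
  if (anyNA(est))
    stop("some truth positions were not imputed", call. = FALSE)
  tv <- as.numeric(truth)
  n <- length(tv)
  if (n < 3L)
    stop("at least 3 evaluated positions are required for correlations",
         call. = FALSE)
  structure(list(
    pearson_r = stats::cor(tv, est),
    kendall_tau = kendall_tau_b(tv, est),
    spearman_rho = stats::cor(rank(tv), rank(est)),
    rss = sum((tv - est)^2),
    n_evaluated = n), class = "evaluation_result")
}

# Tie-corrected Kendall tau-b by pair counting.
kendall_tau_b <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  tx <- sum(dx[up] == 0)
  ty <- sum(dy[up] == 0)
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  s / den
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_result> n = %d: r = %.3f, tau = %.3f, ",
                     "rho = %.3f, RSS = %.2f\n"),
              x$n_evaluated, x$pearson_r, x$kendall_tau, x$spearman_rho,
              x$rss))
  invisible(x)
}
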