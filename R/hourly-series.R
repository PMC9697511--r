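#' Calendar-indexed hourly series
#'
#' An `hourly_series` is the universal carrier of this package: a strictly
#' increasing grid of whole hours, a numeric value per slot (\eqn{\mu g/m^3}
#' for PM2.5), and an explicit validity mask. Invalid slots hold `NA`. After
#' [clean_series()] the grid contains no 29 February and every valid value is
#' strictly positive, so a cleaned year always has 8760 slots.
#'
#' @param start POSIXct (or coercible string) of the first slot, used together
#'   with `length(values)` to build the hourly grid; ignored when `time` is
#'   given.
#' @param values numeric vector of concentrations; `NA` marks missing.
#' @param valid logical validity mask, defaults to `!is.na(values)`.
#' @param time optional POSIXct vector of slot timestamps (whole hours,
#'   strictly increasing); overrides `start`.
#' @param tz time zone of the local clock, default `"UTC"` (the network has a
#'   single local clock and no daylight saving).
#' @return An object of class `hourly_series` with fields `time`, `value`,
#'   `valid` and `imputed`.
#' @export
hourly_series <- function(values, start = NULL, valid = NULL, time = NULL,
                          tz = "UTC") {
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) stop("an hourly series needs at least one slot", call. = FALSE)
  if (is.null(time)) {
    if (is.null(start)) stop("supply either `start` or `time`", call. = FALSE)
    start <- as.POSIXct(start, tz = tz)
    time <- start + 3600 * (seq_len(n) - 1)
  } else {
    time <- as.POSIXct(time, tz = tz)
    if (length(time) != n)
      stop("`time` and `values` must have equal length", call. = FALSE)
  }
  check_calendar_index(time)
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.logical(valid) & !is.na(values)
  values[!valid] <- NA_real_
  structure(list(time = time, value = values, valid = valid,
                 imputed = logical(n)),
            class = "hourly_series")
}

check_calendar_index <- function(time) {
  if (anyNA(time))
    stop("malformed calendar index: NA timestamps", call. = FALSE)
  lt <- as.POSIXlt(time)
  if (any(lt$min != 0L) || any(lt$sec != 0))
    stop("malformed calendar index: timestamps must be whole hours",
         call. = FALSE)
  if (length(time) > 1L && any(diff(as.numeric(time)) <= 0))
    stop("malformed calendar index: timestamps must be strictly increasing",
         call. = FALSE)
  invisible(time)
}

#' @export
length.hourly_series <- function(x) length(x$value)

#' @export
print.hourly_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<hourly_series> %d slots, %s -- %s\n", n,
              format(x$time[1]), format(x$time[n])))
  cat(sprintf("  valid: %d (%.1f%%), imputed: %d\n", sum(x$valid),
              100 * mean(x$valid), sum(x$imputed)))
  invisible(x)
}

#' @export
as.data.frame.hourly_series <- function(x, ...) {
  data.frame(time = x$time, value = x$value, valid = x$valid,
             imputed = x$imputed)
}

#' Calendar labels of an hourly series
#'
#' @param series an [hourly_series()].
#' @return data.frame with integer columns `year`, `month`, `day`, `hour` and
#'   `weekday` (1 = Monday, ..., 7 = Sunday).
#' @export
series_calendar <- function(series) {
  lt <- as.POSIXlt(series$time)
  wd <- lt$wday            # 0 = Sunday
  wd[wd == 0L] <- 7L
  data.frame(year = lt$year + 1900L, month = lt$mon + 1L, day = lt$mday,
             hour = lt$hour, weekday = wd)
}

#' Clean an hourly concentration series
#'
#' Applies the preprocessing rules used throughout the package: observations
#' that are exactly zero or negative are incompatible with a concentration and
#' are marked invalid, and all slots of 29 February are removed so that every
#' year of the grid has 8760 hourly slots. Valid positive values are never
#' altered, which makes the operation idempotent.
#'
#' @param raw an [hourly_series()] with a well-formed calendar index.
#' @param drop_leap_day remove 29 February slots (default `TRUE`).
#' @return list with elements `series` (the cleaned [hourly_series()]) and
#'   `report` (a `cleaning_report` with counts `n_null_deleted`,
#'   `n_negative_deleted`, `n_missing`, `n_valid`).
#' @export
clean_series <- function(raw, drop_leap_day = TRUE) {
  stopifnot(inherits(raw, "hourly_series"))
  value <- raw$value
  valid <- raw$valid
  n_null <- sum(valid & value == 0, na.rm = TRUE)
  n_neg <- sum(valid & value < 0, na.rm = TRUE)
  drop <- valid & (value <= 0)
  valid[drop] <- FALSE
  value[!valid] <- NA_real_
  keep <- rep(TRUE, length(value))
  if (drop_leap_day) {
    lt <- as.POSIXlt(raw$time)
    keep <- !(lt$mon == 1L & lt$mday == 29L)
  }
  out <- structure(list(time = raw$time[keep], value = value[keep],
                        valid = valid[keep], imputed = raw$imputed[keep]),
                   class = "hourly_series")
  report <- structure(list(n_null_deleted = n_null,
                           n_negative_deleted = n_neg,
                           n_missing = sum(!out$valid),
                           n_valid = sum(out$valid)),
                      class = "cleaning_report")
  list(series = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("<cleaning_report> null deleted: %d, negative deleted:",
                     " %d, missing: %d, valid: %d\n"),
              x$n_null_deleted, x$n_negative_deleted, x$n_missing, x$n_valid))
  invisible(x)
}

#' Maximal runs of consecutive missing hours
#'
#' Sensor outages produce runs of consecutive missing hours (an NMAR
#' mechanism); the length of each run drives the imputation policy.
#'
#' @param series an [hourly_series()].
#' @return data.frame with one row per maximal run: `start` (position of the
#'   first missing slot) and `length`, ordered by `start`. Zero rows when the
#'   series is fully valid.
#' @export
find_gap_runs <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  r <- rle(!series$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  miss <- r$values
  data.frame(start = starts[miss], length = r$lengths[miss])
}

#' Grouping views of an hourly series
#'
#' Pools the valid values by year, month (pooled across years), weekday
#' (Monday = first label) or two-hour block of the day (12 blocks pairing
#' hours (0,1), (2,3), ..., (22,23)), mirroring the annual/monthly/weekday/
#' bihourly pooled variables of the exploratory analysis.
#'
#' @param series a cleaned [hourly_series()].
#' @param mode one of `"year"`, `"month"`, `"weekday"`, `"two_hour_block"`.
#' @return named list of numeric vectors; every valid value appears in exactly
#'   one group.
#' @export
group_view <- function(series,
                       mode = c("year", "month", "weekday",
                                "two_hour_block")) {
  mode <- match.arg(mode)
  cal <- series_calendar(series)
  lab <- switch(mode,
    year = as.character(cal$year),
    month = month.abb[cal$month],
    weekday = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[cal$weekday],
    two_hour_block = sprintf("W%d", cal$hour %/% 2L + 1L))
  lev <- switch(mode,
    year = as.character(sort(unique(cal$year))),
    month = month.abb,
    weekday = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"),
    two_hour_block = sprintf("W%d", 1:12))
  ok <- series$valid
  out <- split(series$value[ok], factor(lab[ok], levels = lev))
  out[lengths(out) > 0L | mode %in% c("month", "weekday", "two_hour_block")]
}

#' Centered moving average over valid values
#'
#' Centered window of `window` slots (default 720, one 30-day month of hourly
#' measurements). The mean at each position uses only the valid values inside
#' the window and is reported only where at least `min_frac` of the window is
#' valid; elsewhere the result is `NA`. Slots beyond the series boundary count
#' as invalid.
#'
#' @param series an [hourly_series()].
#' @param window integer window length, >= 1.
#' @param min_frac minimal fraction of valid slots in the window (default 0.5).
#' @return numeric vector, same length as the series.
#' @export
moving_average <- function(series, window = 720L, min_frac = 0.5) {
  stopifnot(inherits(series, "hourly_series"))
  window <- as.integer(window)
  if (is.na(window) || window < 1L)
    stop("`window` must be a positive integer", call. = FALSE)
  n <- length(series)
  v <- ifelse(series$valid, series$value, 0)
  m <- as.numeric(series$valid)
  lo <- window %/% 2L                 # slots before the centre
  hi <- window - 1L - lo              # slots after the centre
  cv <- c(0, cumsum(v))
  cm <- c(0, cumsum(m))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  s <- cv[b + 1L] - cv[a]
  k <- cm[b + 1L] - cm[a]
  out <- ifelse(k > 0, s / k, NA_real_)
  out[k < min_frac * window] <- NA_real_
  out
}

#' One-sided interquartile-range outlier rule
#'
#' Flags values strictly above \eqn{Q_3 + 1.5\,(Q_3 - Q_1)}. The rule is
#' upper-sided only: unusually low values are never flagged. Quantiles use the
#' linear-interpolation empirical convention (`type = 7`), the single
#' convention adopted package-wide.
#'
#' @param values numeric vector with at least 4 finite values.
#' @return logical mask, `TRUE` where a value exceeds the upper fence. `NA`
#'   inputs yield `FALSE`.
#' @export
flag_outliers <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 4L)
    stop("at least 4 finite values are required", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  out <- values > fence
  out[!is.finite(values)] <- FALSE
  out
}

pollution_bands <- data.frame(
  name = c("desirable", "acceptable", "caution", "alert", "alarm",
           "emergency"),
  lower = c(0, 25, 50, 150, 250, 350),
  upper = c(25, 50, 150, 250, 350, Inf))

#' Air-pollution category of a PM2.5 concentration
#'
#' The six half-open bands used for PM2.5 in Quito's air-quality reporting:
#' desirable \[0, 25), acceptable \[25, 50), caution \[50, 150), alert
#' \[150, 250), alarm \[250, 350) and emergency \[350, Inf), all in
#' \eqn{\mu g/m^3}. The bands are exhaustive and mutually exclusive on
#' \[0, Inf).
#'
#' @param value non-negative concentration(s) in \eqn{\mu g/m^3}.
#' @return factor with the six ordered category levels.
#' @export
classify_level <- function(value) {
  if (any(!is.na(value) & value < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  idx <- findInterval(value, pollution_bands$lower)
  factor(pollution_bands$name[idx], levels = pollution_bands$name,
         ordered = TRUE)
}

#' Split a complete unit series into even/odd subsequences
#'
#' A comparison unit of 8192 hourly values (two cleaned semesters of 4096 in
#' calendar order) is split into the even-position part E and the odd-position
#' part O (0-based positions, so E starts at the first element), and each part
#' is halved, giving four subsequences E1, E2, O1, O2 of 2048 values — the
#' four "trimesters" whose wavelet signatures are compared. The mapping is a
#' bijection on positions: the attribute `"positions"` holds, per subsequence,
#' the original 1-based indices, so the input can be reassembled exactly.
#'
#' @param unit_series numeric vector of exactly 8192 values, no missing.
#' @return list of four numeric vectors (`E1`, `E2`, `O1`, `O2`), each of
#'   length 2048, with attribute `"positions"`.
#' @export
split_subsequences <- function(unit_series) {
  n <- length(unit_series)
  if (n != 8192L)
    stop("`unit_series` must have exactly 8192 values", call. = FALSE)
  if (anyNA(unit_series))
    stop("`unit_series` must be complete (no missing values)", call. = FALSE)
  even <- seq(1L, n, by = 2L)   # 0-based even positions
  odd <- seq(2L, n, by = 2L)
  half <- n %/% 4L
  pos <- list(E1 = even[seq_len(half)], E2 = even[half + seq_len(half)],
              O1 = odd[seq_len(half)], O2 = odd[half + seq_len(half)])
  out <- lapply(pos, function(p) unit_series[p])
  attr(out, "positions") <- pos
  out
}

#' Read an hourly series from CSV
#'
#' Two columns: an ISO-8601 timestamp (`2019-03-01T14:00:00` or with a space)
#' and a value; an empty value field is a missing observation.
#'
#' @param path file path.
#' @param tz time zone, default `"UTC"`.
#' @return an [hourly_series()].
#' @export
read_hourly_csv <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected columns: timestamp, value", call. = FALSE)
  ts <- gsub("T", " ", as.character(df[[1]]))
  time <- as.POSIXct(ts, tz = tz, tryFormats = c("%Y-%m-%d %H:%M:%S",
                                                 "%Y-%m-%d %H:%M"))
  hourly_series(as.numeric(df[[2]]), time = time, tz = tz)
}

#' Write an hourly series to CSV
#'
#' @param series an [hourly_series()].
#' @param path file path.
#' @param imputed_col also write the `imputed` flag column (default `TRUE`).
#' @export
write_hourly_csv <- function(series, path, imputed_col = TRUE) {
  df <- data.frame(timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S"),
                   value = series$value)
  if (imputed_col) df$imputed <- series$imputed
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
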