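#' @name neighborhoods
#' @title Candidate neighborhood sets around a missing hour
#'
#' @description Eight index sets of donor hours are built around a missing
#' slot `m` from a cleaned multi-year archive. On a calendar with full
#' coverage their nominal slot counts are 216, 293, 76, 41, 17, 15, 5 and 2.
#' All offsets are exact on the cleaned grid, where every year has 8760
#' hourly slots (no 29 February), so "same date one year earlier" is always
#' 8760 slots back.
#'
#' With `F7` the seven-hour frame (3 h before, the hour itself, 3 h after)
#' and `F3` the three-hour frame, the sets are:
#' \describe{
#'   \item{Set 1 ("month of the missing observation", 216)}{`F7` on each of
#'     the 15 days before and after `m` in `m`'s year, plus the 3 h before
#'     and after `m`.}
#'   \item{Set 2 ("one week in a three-hour frame over five years", 293)}{
#'     `F7` on the 7-day window centred on `m`'s date in each of the 5 prior
#'     years, plus `F7` on the 3 days before/after in `m`'s year, plus the
#'     3 h around `m`.}
#'   \item{Set 3 ("one day with a three-hour frame for five years", 76)}{
#'     `F7` on the day before and the day after `m`'s date in the 5 prior
#'     years, plus the 3 h around `m`.}
#'   \item{Set 4 (41)}{`F7` at `m`'s date in the 5 prior years and in `m`'s
#'     year (excluding `m` itself).}
#'   \item{Set 5 (17)}{`F3` at `m`'s date in the 5 prior years, plus the
#'     hour before and after `m`.}
#'   \item{Set 6 (15)}{`F3` in the 5 prior years only.}
#'   \item{Set 7 (5)}{the same date and hour in each of the 5 prior years.}
#'   \item{Set 8 (2)}{the flanking hours of `m`.}
#' }
#' Slots outside the archive are dropped; slots whose archive value is
#' missing are dropped from `values` but kept in `positions`.
NULL

HOURS_PER_YEAR <- 365L * 24L

assert_archive_grid <- function(archive) {
  stopifnot(inherits(archive, "hourly_series"))
  n <- length(archive)
  lt1 <- as.POSIXlt(archive$time[1])
  if (lt1$mon != 0L || lt1$mday != 1L || lt1$hour != 0L)
    stop("archive must start on 1 January at 00:00", call. = FALSE)
  if (n %% HOURS_PER_YEAR != 0L)
    stop("archive must span whole cleaned years (8760 slots each); ",
         "run clean_series() first", call. = FALSE)
  invisible(archive)
}

# Position of a timestamp (or passthrough of an integer index) on the
# cleaned archive grid.
archive_position <- function(archive, m) {
  if (is.numeric(m) && length(m) == 1L && m == as.integer(m) &&
      !inherits(m, "POSIXt")) {
    p <- as.integer(m)
    if (p < 1L || p > length(archive))
      stop("position outside the archive", call. = FALSE)
    return(p)
  }
  m <- as.POSIXct(m, tz = attr(archive$time, "tzone") %||% "UTC")
  p <- match(as.numeric(m), as.numeric(archive$time))
  if (is.na(p)) stop("timestamp not on the archive grid ",
                     "(is it 29 February, or outside the span?)",
                     call. = FALSE)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

neighborhood_offsets <- function(set_id) {
  Y <- HOURS_PER_YEAR
  H <- 24L
  f7 <- -3:3
  f3 <- -1:1
  frame_hours <- function(anchors, frame)
    as.integer(outer(frame, anchors, `+`))
  switch(as.character(set_id),
    "1" = c(frame_hours(H * c(-15:-1, 1:15), f7), c(-3:-1, 1:3)),
    "2" = c(frame_hours(as.integer(outer(H * (-3:3), -Y * (1:5), `+`)), f7),
            frame_hours(H * c(-3:-1, 1:3), f7), c(-3:-1, 1:3)),
    "3" = c(frame_hours(as.integer(outer(H * c(-1L, 1L), -Y * (1:5), `+`)),
                        f7), c(-3:-1, 1:3)),
    "4" = c(frame_hours(-Y * (1:5), f7), c(-3:-1, 1:3)),
    "5" = c(frame_hours(-Y * (1:5), f3), c(-1L, 1L)),
    "6" = frame_hours(-Y * (1:5), f3),
    "7" = -Y * (1:5),
    "8" = c(-1L, 1L),
    stop("`set_id` must be an integer in 1..8", call. = FALSE))
}

#' Build one candidate neighborhood set
#'
#' @param set_id integer 1 to 8 (see [neighborhoods]).
#' @param m the missing slot: a POSIXct timestamp or an integer position on
#'   the archive grid.
#' @param archive a cleaned multi-year [hourly_series()] starting on 1
#'   January; Sets 2 to 7 need 5 prior years of coverage for the full
#'   nominal slot count.
#' @return object of class `neighborhood_set`: list with `set_id`, `m`
#'   (position), `positions` (sorted slot positions, never including `m`),
#'   `values` (the valid archive values at those slots), `n_slots`,
#'   `n_valid`.
#' @export
build_neighborhood <- function(set_id, m, archive) {
  assert_archive_grid(archive)
  p <- archive_position(archive, m)
  pos <- p + neighborhood_offsets(set_id)
  pos <- pos[pos >= 1L & pos <= length(archive)]
  pos <- sort(pos)
  stopifnot(!anyDuplicated(pos), !p %in% pos)
  ok <- archive$valid[pos]
  structure(list(set_id = as.integer(set_id), m = p, positions = pos,
                 values = archive$value[pos[ok]],
                 n_slots = length(pos), n_valid = sum(ok)),
            class = "neighborhood_set")
}

#' @export
print.neighborhood_set <- function(x, ...) {
  cat(sprintf("<neighborhood_set> Set %d around slot %d: %d slots, %d valid\n",
              x$set_id, x$m, x$n_slots, x$n_valid))
  invisible(x)
}

#' General estimate (GE)
#'
#' The median of the Set-1 neighborhood (the "month of the missing
#' observation"); used as the fallback estimate wherever a narrower set has
#' no usable values.
#'
#' @inheritParams build_neighborhood
#' @return the GE (numeric scalar).
#' @export
general_estimate <- function(m, archive) {
  nb <- build_neighborhood(1L, m, archive)
  if (nb$n_valid == 0L)
    stop("Set 1 has no valid values; GE is undefined here", call. = FALSE)
  stats::median(nb$values)
}

set_suffix <- c("M", "W", "D", "H", "N", "P", "5")

estimator_label <- function(set_id, kind, alpha = NULL) {
  sfx <- set_suffix[set_id]
  switch(kind,
    mean = paste0("Mean", sfx),
    median = if (set_id == 1L) "GE" else paste0("Me", sfx),
    andrews_wave = sprintf("Twa%s(2.4pi)", sfx),
    trimmed_mean = sprintf("T%s(%.1f)", sfx, alpha))
}

#' The 35 labeled estimates of one missing observation
#'
#' Five estimators (mean, median, Andrews' wave Twa(2.4 pi), T(0.1), T(0.2))
#' on each of Sets 1 to 6, four (mean, median, Twa(2.4 pi), T(0.2)) on Set 7,
#' and the flank mean (a one-step linear interpolation) on Set 8: 35 labeled
#' estimates in total. Labels use the set suffixes M, W, D (as printed for
#' the month/week/day sets), 5 for the five-prior-years set, LI for the
#' flank mean, and package-chosen suffixes H, N, P for the three unnamed
#' frame sets. The Set-1 median is labeled GE.
#'
#' When all five Set-7 values are missing, the four Set-7 estimates fall
#' back to the GE; a Set-8 flank that is missing likewise falls back to the
#' GE. An estimate on an empty Set 1 to 6 is `NA`.
#'
#' @inheritParams build_neighborhood
#' @return named numeric vector of 35 estimates.
#' @export
all_estimates <- function(m, archive) {
  assert_archive_grid(archive)
  p <- archive_position(archive, m)
  est <- c(mean = "mean", median = "median", andrews_wave = "andrews_wave")
  out <- c()
  ge <- NULL
  get_ge <- function() {
    if (is.null(ge)) ge <<- general_estimate(p, archive)
    ge
  }
  for (s in 1:6) {
    nb <- build_neighborhood(s, p, archive)
    v <- nb$values
    one <- function(kind, alpha = 0.1)
      if (length(v) == 0L) NA_real_ else robust_location(v, kind,
                                                         alpha = alpha)
    out[estimator_label(s, "mean")] <- one("mean")
    out[estimator_label(s, "median")] <- one("median")
    out[estimator_label(s, "andrews_wave")] <- one("andrews_wave")
    out[estimator_label(s, "trimmed_mean", 0.1)] <- one("trimmed_mean", 0.1)
    out[estimator_label(s, "trimmed_mean", 0.2)] <- one("trimmed_mean", 0.2)
  }
  nb7 <- build_neighborhood(7L, p, archive)
  v7 <- nb7$values
  seven <- function(kind, alpha = 0.2)
    if (length(v7) == 0L) get_ge() else robust_location(v7, kind,
                                                        alpha = alpha)
  out[estimator_label(7L, "mean")] <- seven("mean")
  out[estimator_label(7L, "median")] <- seven("median")
  out[estimator_label(7L, "andrews_wave")] <- seven("andrews_wave")
  out[estimator_label(7L, "trimmed_mean", 0.2)] <- seven("trimmed_mean", 0.2)
  nb8 <- build_neighborhood(8L, p, archive)
  out["LI"] <- if (nb8$n_valid == 2L) mean(nb8$values) else get_ge()
  out
}
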