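#' Wilcoxon rank-sum homogeneity test under a linear transform
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of `x` against the
#' transformed sample `a * y + b`. The shift case `a = 1, b = K` tests the
#' null that the distribution of `x` equals the distribution of `y` plus
#' `K`; a general `(a, b)` tests a linear-transform null such as
#' `X = 0.9 Y + 0.001`. Small untied samples (both sizes below 20) use the
#' exact null distribution; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param a,b linear transform applied to `y` (defaults 1 and 0).
#' @param alpha significance level (default 0.05).
#' @return object of class `shift_test_result`: `reject`, `p_value`, `K`
#'   (`= b` when `a = 1`, otherwise `NA`), `alpha`, `transform = c(a, b)`,
#'   `statistic` (the Mann-Whitney U of `x`).
#' @export
rank_sum_shift_test <- function(x, y, a = 1, b = 0, alpha = 0.05) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 finite values", call. = FALSE)
  yt <- a * y + b
  pooled <- c(x, yt)
  if (length(unique(pooled)) == 1L)
    stop("all observations are tied: the test is undefined", call. = FALSE)
  ties <- anyDuplicated(pooled) > 0L
  exact <- length(x) < 20L && length(yt) < 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, yt, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  structure(list(reject = p < alpha, p_value = p,
                 K = if (a == 1) b else NA_real_, alpha = alpha,
                 transform = c(a = a, b = b),
                 statistic = unname(wt$statistic)),
            class = "shift_test_result")
}

#' @export
print.shift_test_result <- function(x, ...) {
  cat(sprintf(paste0("<shift_test_result> H0: X = %g*Y + %g; U = %g, ",
                     "p = %.4g -> %s at alpha = %g\n"),
              x$transform["a"], x$transform["b"], x$statistic, x$p_value,
              if (x$reject) "reject" else "do not reject", x$alpha))
  invisible(x)
}

#' Calibrate the location shift K that restores homogeneity
#'
#' Searches a grid of shifts for the smallest-magnitude `K` at which the
#' rank-sum test of `x` versus `y + K` does not reject. The grid is centred
#' on the difference of the sample medians and spans three pooled
#' interquartile ranges on each side, at step `grid_step` (the measurement
#' resolution of the series). Candidates are tried in order of increasing
#' magnitude, the negative one first among equal magnitudes, so ties in |K|
#' break toward zero and then toward the negative value.
#'
#' @param x,y numeric samples of size >= 2.
#' @param alpha significance level (default 0.05).
#' @param grid_step grid resolution (default 0.1).
#' @return the calibrated shift `K` (numeric scalar) with attribute
#'   `"p_value"` of the test at `K`.
#' @export
calibrate_shift <- function(x, y, alpha = 0.05, grid_step = 0.1) {
  if (grid_step <= 0) stop("`grid_step` must be > 0", call. = FALSE)
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 values", call. = FALSE)
  centre <- stats::median(x) - stats::median(y)
  span <- 3 * (stats::IQR(x) + stats::IQR(y)) / 2
  span <- max(span, grid_step)
  half <- ceiling(span / grid_step)
  grid <- centre + grid_step * (-half:half)   # grid contains the centre
  grid <- grid[order(abs(grid), sign(grid))]   # |K| ascending, -K before +K
  for (K in grid) {
    res <- rank_sum_shift_test(x, y, a = 1, b = K, alpha = alpha)
    if (!res$reject)
      return(structure(K, p_value = res$p_value))
  }
  stop(sprintf("no shift in [%.4g, %.4g] achieves non-rejection",
               centre - span, centre + span), call. = FALSE)
}
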