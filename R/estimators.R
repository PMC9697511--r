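#' Classical and robust location estimators
#'
#' The location estimators applied to each candidate neighborhood: the mean,
#' the median, the alpha-trimmed mean T(alpha) and Andrews' wave Twa(c), a
#' redescending M-estimator with a sine-shaped weight function.
#'
#' The trimmed mean drops exactly `floor(alpha * n)` observations from each
#' end of the sorted sample (no fractional trimming), so `alpha = 0`
#' reproduces the mean.
#'
#' Andrews' wave is computed iteratively: starting from the median, with
#' scale `s` equal to the unnormalized median absolute deviation, residuals
#' `u_i = (x_i - T) / (c * s)` receive weights `sin(pi u_i) / (pi u_i)` for
#' `|u_i| <= 1` (1 at `u_i = 0`) and 0 beyond, and `T` is updated to the
#' weighted mean until `|dT| < 1e-8` or 100 iterations. When `s = 0` the
#' median is returned. The default tuning constant is `c = 2.4 * pi`.
#'
#' @param values numeric vector, at least one finite value.
#' @param kind one of `"mean"`, `"median"`, `"trimmed_mean"`,
#'   `"andrews_wave"`.
#' @param alpha trim fraction in \[0, 0.5) for the trimmed mean.
#' @param c tuning constant (> 0) for Andrews' wave.
#' @return the location estimate (numeric scalar).
#' @export
robust_location <- function(values,
                            kind = c("mean", "median", "trimmed_mean",
                                     "andrews_wave"),
                            alpha = 0.1, c = 2.4 * pi) {
  kind <- match.arg(kind)
  x <- values[is.finite(values)]
  if (length(x) == 0L)
    stop("at least one finite value is required", call. = FALSE)
  switch(kind,
    mean = mean(x),
    median = stats::median(x),
    trimmed_mean = {
      if (alpha < 0 || alpha >= 0.5)
        stop("`alpha` must lie in [0, 0.5)", call. = FALSE)
      k <- floor(alpha * length(x))
      xs <- sort(x)
      mean(xs[(k + 1L):(length(x) - k)])
    },
    andrews_wave = andrews_wave(x, c))
}

andrews_wave <- function(x, c = 2.4 * pi, tol = 1e-8, max_iter = 100L) {
  if (c <= 0) stop("`c` must be > 0", call. = FALSE)
  med <- stats::median(x)
  s <- stats::median(abs(x - med))          # unnormalized MAD
  if (s == 0) return(med)
  T_ <- med
  for (i in seq_len(max_iter)) {
    u <- (x - T_) / (c * s)
    w <- numeric(length(u))
    inside <- abs(u) <= 1
    nz <- inside & u != 0
    w[nz] <- sin(pi * u[nz]) / (pi * u[nz])
    w[inside & u == 0] <- 1
    if (sum(w) == 0) break
    T_new <- sum(w * x) / sum(w)
    if (abs(T_new - T_) < tol) return(T_new)
    T_ <- T_new
  }
  T_
}
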