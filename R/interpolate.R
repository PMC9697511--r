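#' Fill gaps of an hourly series by interpolation
#'
#' Six interpolation families operating on the slot index: piecewise linear,
#' nearest value, local polynomial of a chosen degree, piecewise cubic
#' Hermite (shape-preserving), modified Akima, cubic spline, and a truncated
#' Fourier (trigonometric least-squares) fit. All interior invalid positions
#' are filled and flagged as imputed; valid positions are never changed.
#' Gaps touching the series boundary are filled by nearest-value extension
#' (no extrapolation).
#'
#' The local fits avoid Runge artifacts on long series: `polynomial` fits a
#' degree-`degree` least-squares polynomial to the valid points within
#' `window` slots of each gap (the window is widened until `degree + 1`
#' support points are available), and `fourier` fits an intercept plus
#' `n_harmonics` sine/cosine pairs of the window's fundamental period to the
#' valid points within a surrounding 30-day window.
#'
#' @param series an [hourly_series()] with at least 2 valid values.
#' @param method one of `"piecewise_linear"`, `"nearest"`, `"polynomial"`,
#'   `"cubic_hermite"`, `"akima"`, `"spline"`, `"fourier"`.
#' @param degree polynomial degree (default 3).
#' @param n_harmonics number of harmonics of the Fourier fit (default 12).
#' @param window half-width in hours of the local polynomial window
#'   (default 24) and of the Fourier window (default 360).
#' @return the filled [hourly_series()]; filled slots have `imputed = TRUE`.
#' @export
interpolate_gaps <- function(series,
                             method = c("piecewise_linear", "nearest",
                                        "polynomial", "cubic_hermite",
                                        "akima", "spline", "fourier"),
                             degree = 3L, n_harmonics = 12L,
                             window = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(series, "hourly_series"))
  vi <- which(series$valid)
  if (length(vi) < 2L)
    stop("at least 2 valid values are required", call. = FALSE)
  gi <- which(!series$valid)
  if (length(gi) == 0L) return(series)
  if (is.null(window)) window <- if (method == "fourier") 360L else 24L

  inner <- gi[gi > min(vi) & gi < max(vi)]
  outer_ <- setdiff(gi, inner)
  xv <- vi
  yv <- series$value[vi]
  fill <- rep(NA_real_, length(inner))
  if (length(inner)) fill <- switch(method,
    piecewise_linear = stats::approx(xv, yv, xout = inner)$y,
    nearest = {
      left <- findInterval(inner, xv)
      right <- pmin(left + 1L, length(xv))
      nearer <- ifelse(inner - xv[left] <= xv[right] - inner, left, right)
      yv[nearer]
    },
    polynomial = local_poly_fill(xv, yv, inner, degree, window),
    cubic_hermite = pracma::pchip(xv, yv, inner),
    akima = pracma::akimaInterp(xv, yv, inner),
    spline = stats::spline(xv, yv, xout = inner, method = "fmm")$y,
    fourier = fourier_fill(xv, yv, inner, n_harmonics, window))
  out <- series
  out$value[inner] <- fill
  if (length(outer_)) {  # boundary gaps: nearest-value extension
    out$value[outer_] <- yv[pmax(1L, findInterval(outer_, xv,
                                                  all.inside = TRUE))]
    lo <- outer_[outer_ < min(vi)]
    hi <- outer_[outer_ > max(vi)]
    out$value[lo] <- yv[1L]
    out$value[hi] <- yv[length(yv)]
  }
  out$valid[gi] <- TRUE
  out$imputed[gi] <- TRUE
  out
}

local_poly_fill <- function(xv, yv, targets, degree, window) {
  degree <- as.integer(degree)
  if (degree < 1L) stop("`degree` must be >= 1", call. = FALSE)
  vapply(targets, function(t) {
    w <- window
    repeat {
      sel <- which(xv >= t - w & xv <= t + w)
      if (length(sel) >= degree + 1L || w > diff(range(xv))) break
      w <- w * 2L
    }
    if (length(sel) < degree + 1L)
      stop("insufficient support points for the polynomial fit",
           call. = FALSE)
    xs <- (xv[sel] - t) / window   # centre and scale for conditioning
    X <- outer(xs, 0:degree, `^`)
    beta <- stats::lm.fit(X, yv[sel])$coefficients
    beta[is.na(beta)] <- 0
    beta[[1]]                      # value at the centred target
  }, numeric(1))
}

fourier_fill <- function(xv, yv, targets, n_harmonics, window) {
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("`n_harmonics` must be >= 1", call. = FALSE)
  vapply(targets, function(t) {
    sel <- which(xv >= t - window & xv <= t + window)
    if (length(sel) < 2L * n_harmonics + 2L)
      sel <- seq_along(xv)  # small series: use all support points
    xs <- xv[sel]
    period <- max(diff(range(xs)), 1)
    h <- seq_len(n_harmonics)
    basis <- function(x) {
      cbind(1, outer(x, h, function(xx, kk) sin(2 * pi * kk * xx / period)),
            outer(x, h, function(xx, kk) cos(2 * pi * kk * xx / period)))
    }
    fit <- stats::lm.fit(basis(xs), yv[sel])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    drop(basis(t) %*% beta)
  }, numeric(1))
}
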