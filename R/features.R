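marginal_stat_names <- c("mean", "sd", "skewness", "kurtosis", "min", "max",
                         "p02", "p98")

#' Eight marginal statistics of a coefficient sequence
#'
#' Mean, standard deviation (sample, n-1 divisor), skewness and kurtosis
#' (standardized third and fourth central moments; kurtosis is non-excess,
#' so a Gaussian gives 3), minimum, maximum, and the 2nd and 98th centiles
#' (linear-interpolation quantiles). A zero-variance sequence gets skewness
#' and kurtosis 0 by convention, with attribute `degenerate = TRUE`.
#'
#' @param values numeric vector, non-empty.
#' @return named numeric vector of length 8.
#' @export
marginal_stats <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n == 0L) stop("empty input", call. = FALSE)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  degenerate <- m2 == 0
  if (degenerate) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  }
  q <- stats::quantile(x, c(0.02, 0.98), names = FALSE, type = 7)
  out <- c(mu, stats::sd(x), skew, kurt, min(x), max(x), q[1], q[2])
  names(out) <- marginal_stat_names
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Cross-scale least-squares prediction of detail coefficients
#'
#' Level-k detail coefficients (k in 1..3) are regressed on the replicated
#' coefficients of the two coarser levels: the predictor matrix Q has the
#' x2-replicated level-(k+1) details as its first column and the
#' x4-replicated level-(k+2) details as its second, and the fitted values
#' are the orthogonal projection `Q (Q'Q)^{-1} Q' D_k`. A rank-deficient Q
#' (e.g. proportional columns) falls back to the minimum-norm least-squares
#' solution via the pseudo-inverse, with a warning; the projection onto the
#' actually spanned column space still holds.
#'
#' @param d_k level-k detail coefficients.
#' @param d_k1 level-(k+1) details, half the length of `d_k`.
#' @param d_k2 level-(k+2) details, a quarter of the length of `d_k`.
#' @return object of class `cross_scale_predictor`: `Q`, `coefficients`,
#'   `fitted` (the projection of `d_k`), `rank`.
#' @export
cross_scale_estimate <- function(d_k, d_k1, d_k2) {
  n <- length(d_k)
  if (length(d_k1) * 2L != n || length(d_k2) * 4L != n)
    stop("lengths must satisfy |D_k| = 2 |D_k+1| = 4 |D_k+2|", call. = FALSE)
  Q <- cbind(upsample_replicate(d_k1, 2L), upsample_replicate(d_k2, 4L))
  sv <- svd(Q)
  tol <- max(dim(Q)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  if (rank < 2L)
    warning("rank-deficient predictor matrix; using the minimum-norm ",
            "least-squares solution", call. = FALSE)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * crossprod(sv$u, d_k))
  fitted <- drop(Q %*% beta)
  structure(list(Q = Q, coefficients = drop(beta), fitted = fitted,
                 rank = rank),
            class = "cross_scale_predictor")
}

#' Log2 error between detail coefficients and their cross-scale prediction
#'
#' `E_k[i] = log2(max(|D_k[i]|, eps)) - log2(max(|D_hat_k[i]|, eps))`. The
#' `eps` floor makes the logarithm well defined at zero coefficients.
#'
#' @param d_k observed detail coefficients.
#' @param d_hat_k fitted coefficients, same length.
#' @param eps positive floor (default 1e-12).
#' @return numeric vector of log2 error terms.
#' @export
log_error <- function(d_k, d_hat_k, eps = 1e-12) {
  if (length(d_k) != length(d_hat_k))
    stop("`d_k` and `d_hat_k` must have equal length", call. = FALSE)
  if (!is.numeric(eps) || eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  log2(pmax(abs(d_k), eps)) - log2(pmax(abs(d_hat_k), eps))
}

#' 80-statistic signature of one 2048-length subsequence
#'
#' The marginal block holds the eight statistics of the raw subsequence, of
#' the detail coefficients of the five decomposition levels and of the
#' fifth-level approximation (7 x 8 = 56 values). The joint block holds the
#' eight statistics of the cross-scale log2 errors E_1, E_2, E_3
#' (3 x 8 = 24 values). Ordering is fixed: raw, D1..D5, A5, E1..E3, each
#' block in the statistic order mean, sd, skewness, kurtosis, min, max,
#' 2nd centile, 98th centile.
#'
#' @param x numeric vector of exactly 2048 values, complete.
#' @param wavelet Daubechies order (default `"db4"`).
#' @param eps floor of [log_error()] (default 1e-12).
#' @return named numeric vector of length 80.
#' @export
subsequence_feature_vector <- function(x, wavelet = "db4", eps = 1e-12) {
  if (length(x) != 2048L)
    stop("a subsequence must have exactly 2048 values", call. = FALSE)
  dec <- dwt_multilevel(x, wavelet = wavelet, levels = 5L)
  D <- dec$details
  E <- lapply(1:3, function(k) {
    cs <- cross_scale_estimate(D[[k]], D[[k + 1]], D[[k + 2]])
    log_error(D[[k]], cs$fitted, eps = eps)
  })
  blocks <- c(list(raw = x), D, list(A5 = dec$approximations[[5]]),
              stats::setNames(E, paste0("E", 1:3)))
  out <- unlist(lapply(names(blocks), function(nm)
    stats::setNames(marginal_stats(blocks[[nm]]),
                    paste(nm, marginal_stat_names, sep = "_"))))
  out
}

#' Feature vector of a comparison unit
#'
#' A unit series is split into even/odd subsequences of 2048 values and the
#' 80-statistic signatures are concatenated subsequence-major: a year of
#' 8192 values gives the subsequences E1, E2, O1, O2 and a 320-vector; a
#' semester of 4096 gives the even and odd halves and a 160-vector; a single
#' 2048 block gives an 80-vector.
#'
#' @param x numeric vector of length 8192, 4096 or 2048, complete.
#' @param unit_label identifier attached to the result (attribute
#'   `"unit_label"`).
#' @inheritParams subsequence_feature_vector
#' @return named numeric vector of length `80 * n_subsequences`.
#' @export
unit_feature_vector <- function(x, wavelet = "db4", eps = 1e-12,
                                unit_label = NULL) {
  n <- length(x)
  if (anyNA(x)) stop("unit series must be complete", call. = FALSE)
  subs <- if (n == 8192L) {
    split_subsequences(x)
  } else if (n == 4096L) {
    list(E = x[seq(1L, n, 2L)], O = x[seq(2L, n, 2L)])
  } else if (n == 2048L) {
    list(S = x)
  } else {
    stop("unit length must be 8192, 4096 or 2048", call. = FALSE)
  }
  out <- unlist(lapply(names(subs), function(nm) {
    fv <- subsequence_feature_vector(subs[[nm]], wavelet, eps)
    stats::setNames(fv, paste(nm, names(fv), sep = "."))
  }))
  if (!is.null(unit_label)) attr(out, "unit_label") <- unit_label
  out
}
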