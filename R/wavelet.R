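# Orthonormal Daubechies scaling filters (sum sqrt(2)), orders 1-10.
# Standard published constants, transcribed at full double precision.
daubechies_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.8068915093110925, 0.45987750211849154,
          -0.13501102001025458, -0.08544127388202666, 0.03522629188570953),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db5 = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.07757149384004572, -0.006241490212798274, -0.012580751999081999,
          0.0033357252854737712),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511,
          -0.0010773010853084796),
  db7 = c(0.07785205408500918, 0.3965393194819173, 0.7291320908462351,
          0.4697822874051931, -0.14390600392856498, -0.22403618499387498,
          0.07130921926683026, 0.08061260915108308, -0.03802993693501441,
          -0.01657454163066688, 0.01255099855609984, 0.0004295779729213665,
          -0.0018016407040474908, 0.00035371379997452024),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953),
  db9 = c(0.038077947363878345, 0.24383467461259034, 0.6048231236901112,
          0.6572880780513005, 0.13319738582500756, -0.2932737832791749,
          -0.09684078322297646, 0.14854074933810638, 0.03072568147933338,
          -0.06763282906132997, 0.00025094711483145197, 0.022361662123679096,
          -0.004723204757751397, -0.00428150368246343, 0.0018476468830562265,
          0.00023038576352319597, -0.0002519631889427101,
          3.93473203162716e-05),
  db10 = c(0.026670057900555554, 0.1881768000776915, 0.5272011889317256,
           0.6884590394536035, 0.2811723436605775, -0.24984642432731538,
           -0.19594627437737705, 0.12736934033579325, 0.09305736460357235,
           -0.07139414716639708, -0.029457536821875813, 0.033212674059341,
           0.0036065535669561697, -0.010733175483330575, 0.001395351747052901,
           0.001992405295185056, -0.0006858566949597116,
           -0.00011646685512928545, 9.358867032006959e-05,
           -1.3264202894521244e-05))

#' Daubechies scaling filter
#'
#' @param wavelet `"db1"` to `"db10"` (db1 is the Haar wavelet).
#' @return numeric vector of scaling-filter coefficients (sums to sqrt(2)).
#' @export
daubechies_filter <- function(wavelet = "db4") {
  h <- daubechies_filters[[wavelet]]
  if (is.null(h))
    stop("unknown wavelet `", wavelet, "`; available: db1..db10",
         call. = FALSE)
  h
}

qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

dwt_step <- function(x, h, g) {
  N <- length(x)
  M <- N %/% 2L
  a <- numeric(M)
  d <- numeric(M)
  base <- 2L * (seq_len(M) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% N + 1L
    a <- a + h[k] * x[idx]
    d <- d + g[k] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h, g) {
  M <- length(a)
  N <- 2L * M
  x <- numeric(N)
  base <- 2L * (seq_len(M) - 1L)
  for (k in seq_along(h)) {
    idx <- (base + (k - 1L)) %% N + 1L
    x[idx] <- x[idx] + h[k] * a + g[k] * d
  }
  x
}

#' Multilevel periodized Daubechies wavelet decomposition
#'
#' Orthonormal discrete wavelet transform with periodic boundary handling,
#' so a dyadic input of length `2^n` yields exactly `2^(n-i)` coefficients
#' at level `i` — the dimensions the cross-scale regression requires. The
#' transform is orthogonal by construction: energy is conserved and the
#' inverse reconstructs the input to machine precision.
#'
#' @param x numeric vector, length a power of two `>= 2^levels`, no missing
#'   values.
#' @param wavelet Daubechies order, `"db1"` to `"db10"` (default `"db4"`).
#' @param levels number of decomposition levels (default 5).
#' @return object of class `wavelet_decomposition`: lists `approximations`
#'   (`A_1..A_levels`) and `details` (`D_1..D_levels`), plus `wavelet`,
#'   `levels` and the input length `n`.
#' @export
dwt_multilevel <- function(x, wavelet = "db4", levels = 5L) {
  levels <- as.integer(levels)
  n <- length(x)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    stop("input length must be a power of two", call. = FALSE)
  if (anyNA(x)) stop("input must not contain missing values", call. = FALSE)
  if (levels < 1L || n < 2^levels)
    stop("input too short for ", levels, " levels", call. = FALSE)
  h <- daubechies_filter(wavelet)
  g <- qmf(h)
  A <- vector("list", levels)
  D <- vector("list", levels)
  cur <- as.numeric(x)
  for (i in seq_len(levels)) {
    st <- dwt_step(cur, h, g)
    A[[i]] <- st$a
    D[[i]] <- st$d
    cur <- st$a
  }
  names(A) <- paste0("A", seq_len(levels))
  names(D) <- paste0("D", seq_len(levels))
  structure(list(approximations = A, details = D, wavelet = wavelet,
                 levels = levels, n = n),
            class = "wavelet_decomposition")
}

#' Inverse of [dwt_multilevel()]
#'
#' @param decomposition a `wavelet_decomposition`.
#' @return the reconstructed numeric vector of length `decomposition$n`.
#' @export
idwt_multilevel <- function(decomposition) {
  stopifnot(inherits(decomposition, "wavelet_decomposition"))
  h <- daubechies_filter(decomposition$wavelet)
  g <- qmf(h)
  lv <- decomposition$levels
  cur <- decomposition$approximations[[lv]]
  for (i in rev(seq_len(lv)))
    cur <- idwt_step(cur, decomposition$details[[i]], h, g)
  cur
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("<wavelet_decomposition> %s, %d levels, n = %d\n", x$wavelet,
              x$levels, x$n))
  cat("  detail lengths:", paste(lengths(x$details), collapse = ", "), "\n")
  invisible(x)
}

#' Replicate coefficients to match a finer scale
#'
#' Coefficients of the next-coarser level are doubled and those two levels
#' coarser are quadrupled, so the three sequences entering the cross-scale
#' regression have the same length.
#'
#' @param coeffs numeric vector.
#' @param factor 2 or 4.
#' @return numeric vector of length `factor * length(coeffs)`, each element
#'   repeated `factor` times consecutively.
#' @export
upsample_replicate <- function(coeffs, factor) {
  if (!factor %in% c(2L, 4L))
    stop("`factor` must be 2 or 4", call. = FALSE)
  rep(coeffs, each = factor)
}
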