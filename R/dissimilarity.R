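#' @name dissimilarity
#' @title Comparing unit signatures
#'
#' @description The feature vectors of the analyzed units (years, semesters,
#' trimesters) form a small n x p matrix (n units, p up to 320). Units are
#' compared through principal component analysis, classical and nonmetric
#' multidimensional scaling, and Euclidean or Hausdorff distance matrices.
NULL

# Make the largest-magnitude component of each column positive, for
# reproducible plots and scores.
fix_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    i <- which.max(abs(M[, j]))
    if (M[i, j] < 0) M[, j] <- -M[, j]
  }
  M
}

#' Principal component analysis of a feature matrix
#'
#' Covariance PCA of centered, unscaled features (no variance scaling).
#' With n units there are at most n - 1 nonzero eigenvalues. Eigenvector
#' signs are fixed so the largest-magnitude loading is positive.
#'
#' @param X numeric matrix, n units x p features (n >= 2, no missing).
#' @param k number of components to return, `1 <= k <= min(n - 1, p)`.
#' @return object of class `embedding`: `points` (n x k scores),
#'   `eigenvalues` (all `min(n-1, p)` covariance eigenvalues, non-increasing),
#'   `var_explained` (fractions summing to 1), `method = "pca"`.
#' @export
pca_embedding <- function(X, k = 2L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L || anyNA(X)) stop("X must have n >= 2 complete rows",
                               call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, ncol(X)))
    stop("`k` must lie in 1..min(n-1, p)", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- fix_signs(pc$rotation)
  scores <- scale(X, center = TRUE, scale = FALSE) %*% rot
  ev <- pc$sdev^2
  structure(list(points = scores[, seq_len(k), drop = FALSE],
                 eigenvalues = ev,
                 var_explained = ev / sum(ev),
                 stress = NULL, method = "pca",
                 labels = rownames(X)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> method = %s, %d points in %d dims\n", x$method,
              nrow(x$points), ncol(x$points)))
  if (!is.null(x$stress)) cat(sprintf("  stress = %.3g\n", x$stress))
  if (!is.null(x$eigenvalues))
    cat("  top eigenvalues:",
        paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", "),
        "\n")
  invisible(x)
}

#' Hausdorff distance between two finite point sets
#'
#' `max( max_a min_b ||a - b||, max_b min_a ||a - b|| )`: the largest
#' distance from a point of one set to its nearest point in the other. A
#' metric on finite point sets; for singletons it reduces to the Euclidean
#' distance.
#'
#' @param A,B numeric matrices (points in rows) or vectors (one coordinate
#'   per point on the line); same ambient dimension, both non-empty.
#' @return the Hausdorff distance (numeric scalar).
#' @export
hausdorff_distance <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, ncol = 1)
  if (is.null(dim(B))) B <- matrix(B, ncol = 1)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("point sets must be non-empty", call. = FALSE)
  if (ncol(A) != ncol(B))
    stop("point sets must share the ambient dimension", call. = FALSE)
  tB <- t(B)
  cross <- apply(A, 1, function(p) sqrt(colSums((tB - p)^2)))
  # cross is |B| x |A|: rows index B, columns index A
  cross <- matrix(cross, nrow = nrow(B))
  max(max(apply(cross, 2, min)), max(apply(cross, 1, min)))
}

#' Pairwise distance matrix between unit signatures
#'
#' Euclidean: the flat l2 distance between whole feature vectors. Hausdorff:
#' each unit's vector is decomposed into a point set first —
#' `subsequence_points` (default) cuts the vector into consecutive blocks of
#' `block_size` (the per-subsequence signatures, e.g. 4 points in 80
#' dimensions for a year), `scalar_components` treats the vector as points
#' on the line. The max-min over 80-dimensional blocks is bounded by the
#' full l2 norm, so Hausdorff entries are systematically smaller than
#' Euclidean ones.
#'
#' @param X numeric matrix of unit signatures (rows).
#' @param metric `"euclidean"` or `"hausdorff"`.
#' @param hausdorff_mode `"subsequence_points"` or `"scalar_components"`.
#' @param block_size block length of `subsequence_points` (default 80).
#' @return symmetric `distance_matrix` (a matrix with attribute `metric`).
#' @export
pairwise_distances <- function(X, metric = c("euclidean", "hausdorff"),
                               hausdorff_mode = c("subsequence_points",
                                                  "scalar_components"),
                               block_size = 80L) {
  metric <- match.arg(metric)
  hausdorff_mode <- match.arg(hausdorff_mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(X))
  } else {
    to_points <- function(v) {
      if (hausdorff_mode == "scalar_components") return(matrix(v, ncol = 1))
      if (length(v) %% block_size != 0L)
        stop("vector length is not a multiple of `block_size`",
             call. = FALSE)
      matrix(v, ncol = block_size, byrow = TRUE)
    }
    pts <- lapply(seq_len(n), function(i) to_points(X[i, ]))
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
      D[i, j] <- D[j, i] <- hausdorff_distance(pts[[i]], pts[[j]])
  }
  dimnames(D) <- list(rownames(X), rownames(X))
  structure(D, metric = metric, class = c("distance_matrix", "matrix"))
}

#' Classical (metric) multidimensional scaling
#'
#' Principal-coordinate analysis: the squared distances are double-centered,
#' `L = -1/2 J D^2 J` with `J = I - (1/n) 1 1'` (the centering is required
#' for the eigendecomposition `L = H B H'` to yield coordinates
#' `Y = H B^{1/2}` that reproduce the distances), and the coordinates are
#' read off the top positive eigenvalues.
#'
#' @param D symmetric non-negative distance matrix (zero diagonal).
#' @param k embedding dimension, `k <= n - 1` (silently capped at the number
#'   of positive eigenvalues).
#' @return an `embedding` with `points`, `eigenvalues` (of L) and
#'   `var_explained` over the positive eigenvalues.
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 1L || k > n - 1L) stop("`k` must lie in 1..n-1", call. = FALSE)
  J <- diag(n) - matrix(1 / n, n, n)
  L <- -0.5 * J %*% (D^2) %*% J
  if (all(D == 0))   # coincident points embed at the origin
    return(structure(list(points = matrix(0, n, k),
                          eigenvalues = rep(0, n),
                          var_explained = rep(0, n), stress = NULL,
                          method = "classical_mds", labels = rownames(D)),
                     class = "embedding"))
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-12
  if (!any(pos))
    stop("no positive eigenvalues: degenerate embedding", call. = FALSE)
  kk <- min(k, sum(pos))
  V <- fix_signs(e$vectors[, seq_len(kk), drop = FALSE])
  Y <- V %*% diag(sqrt(e$values[seq_len(kk)]), kk)
  structure(list(points = Y, eigenvalues = e$values,
                 var_explained = pmax(e$values, 0) / sum(pmax(e$values, 0)),
                 stress = NULL, method = "classical_mds",
                 labels = rownames(D)),
            class = "embedding")
}

#' Kruskal-type stress between dissimilarities and fitted distances
#'
#' `S = sqrt( sum_{i<j} (delta_ij - dhat_ij)^2 / sum_{i<j} delta_ij^2 )`.
#'
#' @param delta dissimilarities: symmetric matrix or upper-triangle vector.
#' @param dhat fitted distances on the same index set.
#' @return the stress (numeric scalar, >= 0).
#' @export
mds_stress <- function(delta, dhat) {
  up <- function(M) if (is.matrix(M)) M[upper.tri(M)] else as.numeric(M)
  d1 <- up(delta)
  d2 <- up(dhat)
  if (length(d1) != length(d2))
    stop("`delta` and `dhat` must match in size", call. = FALSE)
  if (all(d1 == 0)) stop("`delta` must not be all zero", call. = FALSE)
  sqrt(sum((d1 - d2)^2) / sum(d1^2))
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal-style iteration initialized from [classical_mds()]: disparities
#' are the isotonic (pool-adjacent-violators) regression of the
#' configuration distances on the rank order of the dissimilarities, the
#' configuration moves by a Guttman (majorization) transform toward the
#' disparities, and after every move the configuration is rescaled by the
#' factor that minimizes the stress against the dissimilarities. The best
#' configuration seen is retained, so the best-so-far stress trajectory is
#' non-increasing and the final stress never exceeds that of the
#' classical-MDS initialization. Deterministic given `seed`.
#'
#' @param D dissimilarity matrix (n >= 3).
#' @param k embedding dimension (default 2).
#' @param seed integer seed (used only to jitter coincident points).
#' @param max_iter,tol iteration cap (default 500) and minimal stress
#'   improvement (default 1e-12).
#' @return an `embedding` with `points`, `stress` (computed by
#'   [mds_stress()] on the returned configuration), `dhat` (the
#'   configuration distances), `delta`, `iterations`, `converged`.
#' @export
nonmetric_mds <- function(D, k = 2L, seed = 1L, max_iter = 500L,
                          tol = 1e-12) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("nonmetric MDS needs n >= 3 units", call. = FALSE)
  delta <- D[upper.tri(D)]
  if (all(delta == 0)) stop("all dissimilarities are zero", call. = FALSE)
  Y <- with_seed(seed, {
    Y0 <- classical_mds(D, k)$points
    if (ncol(Y0) < k)   # pad degenerate initializations
      Y0 <- cbind(Y0, matrix(stats::rnorm(n * (k - ncol(Y0)), 0,
                                          1e-6 * max(D)), n))
    Y0
  })
  pair_dist <- function(Y) {
    M <- as.matrix(stats::dist(Y))
    M[upper.tri(M)]
  }
  report_stress <- function(d) {
    s <- sum(delta * d) / sum(d^2)           # optimal scale of the config
    list(scale = s, stress = sqrt(sum((delta - s * d)^2) / sum(delta^2)))
  }
  ord <- order(delta)
  d <- pair_dist(Y)
  cur <- report_stress(d)
  best_Y <- Y * cur$scale
  best_stress <- cur$stress
  iter <- 0L
  converged <- best_stress < tol
  raw_prev <- Inf
  while (iter < max_iter && !converged) {
    iter <- iter + 1L
    # isotonic disparities of d in the delta order
    dhat <- numeric(length(d))
    dhat[ord] <- stats::isoreg(seq_along(ord), d[ord])$yf
    raw <- sum((d - dhat)^2) / sum(d^2)   # majorized (Kruskal) objective
    # Guttman transform toward the disparities
    ratio <- ifelse(d > 0, dhat / d, 0)
    Bm <- matrix(0, n, n)
    Bm[upper.tri(Bm)] <- -ratio
    Bm <- Bm + t(Bm)
    diag(Bm) <- -rowSums(Bm)
    Ynew <- Bm %*% Y / n
    dnew <- pair_dist(Ynew)
    if (all(dnew == 0)) break
    new <- report_stress(dnew)
    if (new$stress < best_stress) {   # keep the best configuration seen
      best_stress <- new$stress
      best_Y <- Ynew * new$scale
    }
    Y <- Ynew
    d <- dnew
    if (raw_prev - raw < tol || best_stress < tol) {
      converged <- TRUE
      break
    }
    raw_prev <- raw
  }
  if (iter == max_iter && !converged)
    warning("nonmetric MDS did not converge in ", max_iter,
            " iterations; returning the best configuration", call. = FALSE)
  dhat_final <- pair_dist(best_Y)
  structure(list(points = best_Y, stress = mds_stress(delta, dhat_final),
                 dhat = dhat_final, delta = delta, eigenvalues = NULL,
                 var_explained = NULL, iterations = iter,
                 converged = converged, method = "nonmetric_mds",
                 labels = rownames(D)),
            class = "embedding")
}
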