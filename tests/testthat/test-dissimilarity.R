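test_that("PCA of few units has at most n - 1 nonzero eigenvalues", {
  set.seed(20)
  X <- matrix(rnorm(6 * 320), 6, 320)
  emb <- pca_embedding(X, k = 2)
  ev <- emb$eigenvalues
  expect_lt(max(ev[-(1:5)]) / ev[1], 1e-10)
  expect_equal(sum(emb$var_explained), 1, tolerance = 1e-10)
  expect_true(all(diff(ev) <= 1e-8))
})

test_that("duplicated units map to identical scores", {
  set.seed(21)
  X <- matrix(rnorm(5 * 40), 5, 40)
  X[5, ] <- X[2, ]
  emb <- pca_embedding(X, k = 3)
  expect_equal(emb$points[5, ], emb$points[2, ], tolerance = 1e-10)
})

test_that("collinear points put all variance on the first component", {
  t <- c(-1, 0, 2)
  dir <- rnorm(50)
  X <- outer(t, dir)
  emb <- pca_embedding(X, k = 2)
  expect_equal(emb$var_explained[1], 1, tolerance = 1e-10)
  expect_error(pca_embedding(X, k = 10), "k")
})

test_that("Hausdorff distance matches its definition and pracma's oracle", {
  A <- matrix(c(0, 1), ncol = 1)
  B <- matrix(c(0, 3), ncol = 1)
  expect_equal(hausdorff_distance(A, B), 2)
  expect_equal(hausdorff_distance(A, A), 0)
  a <- matrix(rnorm(3), 1)
  b <- matrix(rnorm(3), 1)
  expect_equal(hausdorff_distance(a, b), sqrt(sum((a - b)^2)))
  set.seed(22)
  for (i in 1:10) {
    P <- matrix(rnorm(8 * 4), 8, 4)
    Q <- matrix(rnorm(6 * 4), 6, 4)
    expect_equal(hausdorff_distance(P, Q), pracma::hausdorff_dist(P, Q),
                 tolerance = 1e-10)
  }
  expect_error(hausdorff_distance(matrix(0, 0, 2), B), "non-empty")
})

test_that("Hausdorff distance is a metric on point sets", {
  set.seed(23)
  sets <- replicate(6, matrix(rnorm(10 * 3), 10, 3), simplify = FALSE)
  for (i in 1:6) for (j in 1:6) {
    dij <- hausdorff_distance(sets[[i]], sets[[j]])
    expect_equal(dij, hausdorff_distance(sets[[j]], sets[[i]]))
    if (i == j) expect_equal(dij, 0)
    for (k in 1:6)
      expect_lte(dij, hausdorff_distance(sets[[i]], sets[[k]]) +
                        hausdorff_distance(sets[[k]], sets[[j]]) + 1e-12)
  }
})

test_that("pairwise distances honour metric and decomposition mode", {
  set.seed(24)
  X <- matrix(rnorm(4 * 320), 4, 320)
  X[2, ] <- X[1, ]
  De <- pairwise_distances(X, "euclidean")
  Dh <- pairwise_distances(X, "hausdorff")
  for (D in list(De, Dh)) {
    expect_true(isSymmetric(unclass(D)))
    expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
    expect_equal(D[1, 2], 0)
  }
  # block max-min is bounded by the full l2 norm
  expect_true(all(Dh <= De + 1e-9))
  D2 <- pairwise_distances(X[1:2, ], "euclidean")
  expect_equal(dim(D2), c(2L, 2L))
  expect_error(pairwise_distances(X[, 1:30], "hausdorff"), "block_size")
})

test_that("classical MDS round-trips Euclidean distances", {
  # points on a line at 0, 1, 3
  D <- as.matrix(dist(c(0, 1, 3)))
  emb <- classical_mds(D, k = 1)
  expect_equal(as.matrix(dist(emb$points)), D, tolerance = 1e-8,
               ignore_attr = TRUE)

  set.seed(25)
  P <- matrix(rnorm(7 * 3), 7, 3)
  D3 <- as.matrix(dist(P))
  emb3 <- classical_mds(D3, k = 3)
  expect_equal(as.matrix(dist(emb3$points)), D3, tolerance = 1e-6,
               ignore_attr = TRUE)
  # agreement with the reference implementation
  ref <- cmdscale(D3, k = 3)
  expect_equal(as.matrix(dist(emb3$points)), as.matrix(dist(ref)),
               tolerance = 1e-8, ignore_attr = TRUE)

  zero <- classical_mds(matrix(0, 4, 4), k = 2)
  expect_true(all(zero$points == 0))
})

test_that("stress follows the normalized residual formula", {
  expect_equal(mds_stress(1, 1), 0)
  expect_equal(mds_stress(1, 0), 1)
  expect_equal(mds_stress(c(3, 4), c(3, 0)), 4 / 5)
  M <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(mds_stress(M, M), 0)
  expect_error(mds_stress(c(0, 0), c(1, 2)), "zero")
  expect_error(mds_stress(1:3, 1:2), "match")
})

test_that("nonmetric MDS drives stress to zero on embeddable distances", {
  set.seed(26)
  P <- matrix(rnorm(6 * 2), 6, 2)
  D <- as.matrix(dist(P))
  emb <- nonmetric_mds(D, k = 2, seed = 1)
  expect_lt(emb$stress, 1e-6)
  # the reported stress is reproducible from the returned configuration
  expect_equal(emb$stress, mds_stress(emb$delta, emb$dhat))
  # determinism under a fixed seed
  emb2 <- nonmetric_mds(D, k = 2, seed = 1)
  expect_identical(emb$points, emb2$points)
  # rank order of pairwise distances is recovered exactly
  expect_equal(order(emb$dhat), order(D[upper.tri(D)]))
})

test_that("nonmetric MDS never ends above its classical initialization", {
  set.seed(27)
  for (i in 1:5) {
    X <- matrix(rnorm(7 * 15), 7, 15)
    D <- as.matrix(dist(X))
    init <- classical_mds(D, k = 2)$points
    d0 <- as.matrix(dist(init))[upper.tri(D)]
    s0 <- sum(D[upper.tri(D)] * d0) / sum(d0^2)
    init_stress <- mds_stress(D[upper.tri(D)], s0 * d0)
    # non-convergence on hard geometries is allowed: best-so-far is returned
    emb <- suppressWarnings(nonmetric_mds(D, k = 2, seed = i))
    expect_lte(emb$stress, init_stress + 1e-12)
  }
})

test_that("nonmetric MDS agrees with the reference on an easy geometry", {
  set.seed(28)
  P <- matrix(rnorm(8 * 2), 8, 2)
  D <- as.matrix(dist(P))
  emb <- nonmetric_mds(D, k = 2, seed = 1)
  ref <- MASS::isoMDS(as.dist(D), k = 2, trace = FALSE)
  # both recover the configuration: embedding distances correlate ~1
  expect_gt(cor(emb$dhat, as.matrix(dist(ref$points))[upper.tri(D)]),
            0.9999)
  expect_error(nonmetric_mds(as.matrix(dist(c(0, 1))), k = 1), "n >= 3")
})
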