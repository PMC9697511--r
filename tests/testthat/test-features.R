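test_that("marginal statistics match hand computation", {
  st <- marginal_stats(c(1, 2, 3, 4, 5))
  expect_equal(unname(st["mean"]), 3)
  expect_equal(unname(st["sd"]), sqrt(2.5))
  expect_equal(unname(st["skewness"]), 0)
  expect_equal(unname(st["kurtosis"]), 6.8 / 4)  # m4/m2^2 = 6.8 / 2^2
  expect_equal(unname(st["min"]), 1)
  expect_equal(unname(st["max"]), 5)
  expect_equal(unname(st[c("p02", "p98")]),
               unname(quantile(1:5, c(0.02, 0.98), type = 7)))
  # symmetric samples have zero skewness
  x <- c(-3, -1, 0, 1, 3)
  expect_lt(abs(marginal_stats(x)["skewness"]), 1e-12)
  # ordering invariant of the block
  expect_true(st["min"] <= st["p02"] && st["p02"] <= st["p98"] &&
                st["p98"] <= st["max"])
})

test_that("zero-variance sequences use the degenerate convention", {
  st <- marginal_stats(rep(2.5, 10))
  expect_equal(unname(st), c(2.5, 0, 0, 0, 2.5, 2.5, 2.5, 2.5),
               ignore_attr = TRUE)
  expect_true(isTRUE(attr(st, "degenerate")))
  expect_error(marginal_stats(numeric(0)), "empty")
})

test_that("cross-scale projection solves the normal equations", {
  d_k <- c(1, 2, 3, 4)
  d_k1 <- c(1, 2)
  d_k2 <- 1
  cs <- cross_scale_estimate(d_k, d_k1, d_k2)
  # independent 2x2 normal-equation oracle
  Q <- cbind(c(1, 1, 2, 2), c(1, 1, 1, 1))
  beta <- solve(t(Q) %*% Q, t(Q) %*% d_k)
  expect_equal(cs$fitted, drop(Q %*% beta), tolerance = 1e-12)
  expect_equal(unname(cs$coefficients), drop(beta), tolerance = 1e-12)
  # residual orthogonal to the columns of Q
  expect_lt(max(abs(t(Q) %*% (d_k - cs$fitted))), 1e-10)
})

test_that("the projection is idempotent and fixes its column space", {
  set.seed(6)
  d_k1 <- rnorm(8)
  d_k2 <- rnorm(4)
  in_space <- 2 * upsample_replicate(d_k1, 2) - upsample_replicate(d_k2, 4)
  cs <- cross_scale_estimate(in_space, d_k1, d_k2)
  expect_equal(cs$fitted, in_space, tolerance = 1e-8)
  d_k <- rnorm(16)
  once <- cross_scale_estimate(d_k, d_k1, d_k2)$fitted
  twice <- cross_scale_estimate(once, d_k1, d_k2)$fitted
  expect_equal(twice, once, tolerance = 1e-10)
})

test_that("rank-deficient predictors fall back to the pseudo-inverse", {
  d_k1 <- c(1, 2)
  d_k2 <- 1
  # second column proportional to the first
  expect_warning(cs <- cross_scale_estimate(c(1, 1, 1, 1), c(1, 1), 1),
                 "rank-deficient")
  expect_equal(cs$fitted, rep(1, 4), tolerance = 1e-10)
  expect_error(cross_scale_estimate(1:4, 1:2, 1:2), "lengths")
})

test_that("log2 errors respect the eps floor", {
  d <- c(1, 2, 4)
  expect_equal(log_error(d, d), rep(0, 3))
  expect_equal(log_error(c(2, 4), c(1, 2)), c(1, 1))
  eps <- 1e-12
  expect_equal(log_error(0, eps, eps = eps), 0)
  expect_equal(log_error(c(0, 1), c(0, 1)), c(0, 0))
  expect_error(log_error(1:3, 1:2), "equal length")
  expect_error(log_error(1, 1, eps = 0), "eps")
})

test_that("subsequence signatures have the documented 56 + 24 layout", {
  set.seed(10)
  x <- exp(rnorm(2048, log(14), 0.4))
  fv <- subsequence_feature_vector(x)
  expect_length(fv, 80L)
  blocks <- sub("_[^_]+$", "", names(fv))
  expect_equal(unique(blocks), c("raw", "D1", "D2", "D3", "D4", "D5", "A5",
                                 "E1", "E2", "E3"))
  expect_equal(as.vector(table(factor(blocks, levels = unique(blocks)))),
               rep(8L, 10))
  # 56 marginal + 24 joint
  expect_length(fv[grepl("^(raw|D[1-5]|A5)_", names(fv))], 56L)
  expect_length(fv[grepl("^E[1-3]_", names(fv))], 24L)
  expect_error(subsequence_feature_vector(rnorm(1024)), "2048")
})

test_that("detail and joint blocks are shift-invariant, raw blocks shift", {
  set.seed(14)
  x <- exp(rnorm(2048, log(14), 0.4))
  f0 <- subsequence_feature_vector(x)
  fc <- subsequence_feature_vector(x + 100)
  detail <- grepl("^(D[1-5]|E[1-3])_", names(f0))
  expect_equal(fc[detail], f0[detail], tolerance = 1e-6)
  shifty <- paste0("raw_", c("mean", "min", "max", "p02", "p98"))
  expect_equal(unname(fc[shifty] - f0[shifty]), rep(100, 5),
               tolerance = 1e-9)
  expect_equal(fc["raw_sd"], f0["raw_sd"], tolerance = 1e-9)
})

test_that("scaling the input scales location statistics and nothing else", {
  set.seed(15)
  x <- exp(rnorm(2048, log(14), 0.4))
  f0 <- subsequence_feature_vector(x)
  f2 <- subsequence_feature_vector(2 * x)
  loc <- grepl("^(raw|D[1-5]|A5)_(mean|sd|min|max|p02|p98)$", names(f0))
  expect_equal(f2[loc], 2 * f0[loc], tolerance = 1e-8)
  shape <- grepl("^(raw|D[1-5]|A5)_(skewness|kurtosis)$", names(f0))
  expect_equal(f2[shape], f0[shape], tolerance = 1e-8)
  joint <- grepl("^E[1-3]_", names(f0))
  expect_equal(f2[joint], f0[joint], tolerance = 1e-6)
})

test_that("unit vectors concatenate subsequence signatures in order", {
  set.seed(16)
  x <- exp(rnorm(8192, log(14), 0.4))
  fv <- unit_feature_vector(x, unit_label = "X1")
  expect_length(fv, 320L)
  expect_equal(attr(fv, "unit_label"), "X1")
  subs <- split_subsequences(x)
  expect_equal(unname(fv[1:80]),
               unname(subsequence_feature_vector(subs$E1)))
  expect_equal(unname(fv[241:320]),
               unname(subsequence_feature_vector(subs$O2)))
  # determinism
  expect_identical(fv, unit_feature_vector(x, unit_label = "X1"))
  # semester and trimester units
  expect_length(unit_feature_vector(x[1:4096]), 160L)
  expect_length(unit_feature_vector(x[1:2048]), 80L)
  expect_error(unit_feature_vector(x[1:1000]), "8192, 4096 or 2048")
})
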