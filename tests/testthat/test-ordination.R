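test_that("pca matches a brute-force covariance eigendecomposition", {
  set.seed(31)
  m <- matrix(rnorm(24), 6, 4)
  res <- pca(m)
  # oracle: eigen of the hand-computed covariance of centered observations
  xc <- sweep(m, 2, colMeans(m))
  e <- eigen(t(xc) %*% xc / (nrow(m) - 1), symmetric = TRUE)
  expect_equal(res$eigenvalues, e$values, tolerance = 1e-9)
  for (a in 1:4)
    expect_equal(abs(res$coordinates[, a]), abs(xc %*% e$vectors[, a])[, 1],
                 tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(res$eigenvalues), sum(apply(m, 2, var)), tolerance = 1e-9)
})

test_that("pca handles rank-1 and isotropic data as the geometry dictates", {
  line <- cbind(1:6, 2 * (1:6))
  res <- pca(line)
  expect_equal(res$eigenvalues[1], sum(apply(line, 2, var)), tolerance = 1e-9)
  expect_lt(res$eigenvalues[2], 1e-9)
  expect_equal(scree(res)$variance_fraction[1], 1, tolerance = 1e-9)

  iso <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_equal(diff(pca(iso)$eigenvalues), 0, tolerance = 1e-9)
  expect_error(pca(matrix(1, 1, 3)), ">= 2")
})

test_that("pcoa recovers a planted configuration and reproduces pca fractions", {
  set.seed(17)
  pts <- matrix(rnorm(14), 7, 2)
  res <- pcoa(euclidean_dist(t(pts)))
  expect_lt(procrustes_residual(pts, res$coordinates[, 1:2]), 1e-6)

  m <- matrix(rnorm(30), 6, 5)
  vf_pcoa <- pcoa(euclidean_dist(t(m)))$variance_fraction
  vf_pca <- pca(m)$variance_fraction
  expect_equal(sort(vf_pcoa, decreasing = TRUE)[1:4],
               sort(vf_pca, decreasing = TRUE)[1:4], tolerance = 1e-9)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("pcoa agrees with the ape oracle on a random dissimilarity", {
  skip_if_not_installed("ape")
  ct <- random_table(9, 6, seed = 23)
  d <- aitchison_dist(ct)
  res <- pcoa(d)
  ora <- ape::pcoa(as.dist(d$values))
  k <- ncol(ora$vectors)
  expect_equal(res$eigenvalues[1:k], ora$values$Eigenvalues[1:k],
               tolerance = 1e-8)
  for (a in 1:2)
    expect_equal(abs(res$coordinates[, a]), abs(ora$vectors[, a]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("non-metric bray-curtis input yields flagged negative eigenvalues", {
  d <- bray_curtis(bray_curtis_counterexample())
  expect_warning(res <- pcoa(d), "non-metric")
  expect_true(any(res$eigenvalues < 0))
  # negative axes contribute nothing to coordinates or variance fractions
  expect_true(all(res$coordinates[, res$eigenvalues < 0] == 0))
  expect_true(all(res$variance_fraction >= 0))
})

test_that("stress matches its closed form and vanishes only at equality", {
  d <- rbind(c(0, 1, 2), c(1, 0, 0), c(2, 0, 0))
  expect_equal(stress(d, d), 0)
  d2 <- rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
  expect_equal(stress(d, d2), sqrt(1 / 5), tolerance = 1e-12)
  # 1-parameter scan: minimized at the true scaling, varies continuously
  s <- sapply(seq(0.5, 1.5, 0.05), function(a) stress(d, a * d))
  expect_equal(which.min(s), 11L)
  expect_lt(max(abs(diff(s))), 0.2)
  expect_error(stress(matrix(0, 2, 2), matrix(0, 2, 2)), "all-zero")
})

test_that("mds embeds exact low-rank data at zero stress, deterministically", {
  set.seed(41)
  pts <- matrix(rnorm(12), 6, 2)
  d <- euclidean_dist(t(pts))
  res <- mds(d, ndim = 2, seed = 7, n_restarts = 3)
  expect_lt(res$stress, 1e-6)
  res2 <- mds(d, ndim = 2, seed = 7, n_restarts = 3)
  expect_identical(res$coordinates, res2$coordinates)
  # self-consistency: reported stress is the formula applied to its output
  expect_equal(res$stress,
               stress(d$values, as.matrix(dist(res$coordinates))),
               tolerance = 1e-12)
  expect_error(mds(d, ndim = 6), "smaller")
})

test_that("mds stress is non-increasing in the embedding dimension", {
  set.seed(43)
  m <- matrix(rnorm(40), 8, 5)
  d <- euclidean_dist(t(m))
  s2 <- mds(d, ndim = 2, seed = 1, n_restarts = 5)$stress
  s7 <- mds(d, ndim = 7, seed = 1, n_restarts = 5)$stress
  expect_lte(s7, s2 + 1e-9)
})

test_that("scree fractions are normalized, descending, and refuse mds input", {
  res <- pca(matrix(rnorm(30), 6, 5))
  tab <- scree(res)
  expect_equal(sum(tab$variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(tab$variance_fraction) <= 1e-12))
  expect_equal(tab$cumulative[nrow(tab)], 1, tolerance = 1e-9)
  md <- mds(euclidean_dist(matrix(rnorm(20), 4, 5), compare = "taxa"),
            ndim = 2, n_restarts = 2)
  expect_error(scree(md), "pca or pcoa")
})
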