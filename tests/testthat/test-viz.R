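test_that("SVD compression matches a covariance eigendecomposition oracle", {
  set.seed(51)
  X <- matrix(rnorm(20 * 8), 20, 8)
  out <- svdCompress(X, 4)
  ev <- eigen(cov(X), symmetric = TRUE)
  scOracle <- sweep(X, 2, colMeans(X)) %*% ev$vectors[, 1:4]
  for (j in 1:4)   # scores defined up to sign
    expect_equal(abs(out$scores[, j]), abs(scOracle[, j]), tolerance = 1e-8)
  expect_equal(out$explained, (ev$values / sum(ev$values))[1:4],
               tolerance = 1e-10)
  expect_true(all(diff(out$explained) <= 1e-12))
})

test_that("rank-2 input leaves no variance beyond two components", {
  set.seed(52)
  Z <- matrix(rnorm(15 * 2), 15, 2)
  X <- Z %*% matrix(rnorm(2 * 6), 2, 6)
  out <- svdCompress(X, 5)
  expect_lt(sum(out$explained[3:5]), 1e-10)
  expect_error(svdCompress(X, 20), "exceeds")
})

test_that("reconstruction error decreases monotonically in component count", {
  set.seed(53)
  X <- matrix(rnorm(18 * 10), 18, 10)
  Xc <- sweep(X, 2, colMeans(X))
  errs <- sapply(1:8, function(k) {
    sv <- svd(Xc)
    Xk <- sv$u[, 1:k, drop = FALSE] %*% diag(sv$d[1:k], k) %*%
      t(sv$v[, 1:k, drop = FALSE])
    sum((Xc - Xk)^2)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("discriminant coordinates separate separated clusters and flip with labels", {
  set.seed(54)
  y <- rep(c(1, 0), each = 15)
  X <- matrix(rnorm(30 * 5), 30, 5)
  X[y == 1, ] <- X[y == 1, ] + 3
  lda <- ldaCoordinates(X, y)
  co <- lda$coordinates
  gap <- abs(mean(co[y == 1, 1]) - mean(co[y == 0, 1]))
  within <- sqrt(mean(c(var(co[y == 1, 1]), var(co[y == 0, 1]))))
  expect_gt(gap, 5 * within)
  # swapping labels flips only the discriminant axis
  ldaS <- ldaCoordinates(X, 1 - y)
  expect_equal(ldaS$coordinates[, 1], -co[, 1], tolerance = 1e-8)
  expect_equal(abs(ldaS$coordinates[, 2]), abs(co[, 2]), tolerance = 1e-8)
})

test_that("the discriminant axis is invariant to feature rescaling", {
  set.seed(55)
  y <- rep(c(1, 0), each = 12)
  X <- matrix(rnorm(24 * 4), 24, 4)
  X[y == 1, 1] <- X[y == 1, 1] + 2
  co1 <- ldaCoordinates(X, y)$coordinates
  Xs <- sweep(X, 2, c(10, 0.1, 3, 1), `*`)
  co2 <- ldaCoordinates(Xs, y)$coordinates
  # coordinate 1 is the Fisher score in unit within-class SD: exactly
  # invariant under invertible diagonal rescaling
  expect_equal(co1[, 1], co2[, 1], tolerance = 1e-8)
  # coordinate 2 stays finite, unit within-class SD, within-class
  # uncorrelated with coordinate 1
  R <- co1
  R[y == 1, ] <- sweep(co1[y == 1, ], 2, colMeans(co1[y == 1, ]))
  R[y == 0, ] <- sweep(co1[y == 0, ], 2, colMeans(co1[y == 0, ]))
  expect_lt(abs(sum(R[, 1] * R[, 2])) / (nrow(R) - 2), 1e-8)
  expect_equal(sum(R[, 2]^2) / (nrow(R) - 2), 1, tolerance = 1e-8)
})

test_that("confidence ellipses behave at the boundaries and cover as n grows", {
  set.seed(56)
  P <- matrix(rnorm(2000 * 2), 2000, 2)
  ell <- confidenceEllipse(P, level = 0.95)
  md <- stats::mahalanobis(P, ell$center, ell$shape)
  expect_lt(abs(mean(md <= ell$radius2) - 0.95), 0.02)
  # isotropic cloud -> near-circular shape
  ev <- eigen(ell$shape)$values
  expect_lt(ev[1] / ev[2], 1.2)
  # level 0 degenerates to the center point
  expect_equal(confidenceEllipse(P, level = 0)$radius2, 0)
  expect_error(confidenceEllipse(P[1:2, ]), ">= 3")
  expect_error(confidenceEllipse(cbind(1:5, 2 * (1:5))), "degenerate")
})

test_that("the projection pipeline separates planted effects but not the null", {
  cfg <- runConfig()
  dsE <- generateDataset(quickConfig(seed = 57, effect_size = 2.0))$spectra
  dsN <- generateDataset(quickConfig(seed = 57, effect_size = 0))$spectra
  dist2 <- function(ds) {
    fm <- preprocessSpectra(ds, cfg)
    flt <- filterFeatures(fm, threshold = 0.3)$filtered
    pr <- discriminantProjection(flt, nComponents = 10)
    cE <- pr$ellipses$FRI$center; cC <- pr$ellipses$control$center
    sum((cE - cC)^2)
  }
  expect_gt(dist2(dsE), 0)   # centers separate under the planted effect
  pr <- discriminantProjection(
    filterFeatures(preprocessSpectra(dsE, cfg), threshold = 0.3)$filtered,
    nComponents = 10)
  expect_true(all(is.finite(pr$coordinates)))
  expect_true(all(pr$explained > 0))
})
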