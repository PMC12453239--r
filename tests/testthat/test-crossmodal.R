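test_that("a shared column forces the first canonical correlation to one", {
  set.seed(61)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Y <- cbind(X[, 2], matrix(rnorm(30 * 3), 30, 3))
  r <- ccaFit(X, Y)
  expect_equal(r@correlations[1], 1, tolerance = 1e-8)
})

test_that("a two-variable instance matches an explicit grid-search oracle", {
  set.seed(62)
  X <- matrix(rnorm(40 * 2), 40, 2)
  Y <- matrix(rnorm(40 * 2), 40, 2) + 0.5 * X
  r <- ccaFit(X, Y, k = 1)
  ang <- seq(0, pi, length.out = 721)
  best <- 0
  Xs <- scale(X); Ys <- scale(Y)
  for (a in ang) for (b in ang) {
    cr <- abs(cor(Xs %*% c(cos(a), sin(a)), Ys %*% c(cos(b), sin(b)))[1, 1])
    if (cr > best) best <- cr
  }
  expect_equal(r@correlations[1], best, tolerance = 1e-3)
})

test_that("canonical correlations are invariant to affine column rescaling", {
  set.seed(63)
  X <- matrix(rnorm(25 * 3), 25, 3)
  Y <- matrix(rnorm(25 * 3), 25, 3) + X
  r1 <- ccaFit(X, Y)@correlations
  X2 <- sweep(X, 2, c(7, 0.2, 3), `*`) + 5
  Y2 <- sweep(Y, 2, c(0.5, 9, 2), `*`) - 1
  r2 <- ccaFit(X2, Y2)@correlations
  expect_equal(r1, r2, tolerance = 1e-8)
  expect_true(all(diff(r1) <= 1e-8))
  # agrees with the base cancor on a well-conditioned instance
  cc <- cancor(scale(X), scale(Y))
  expect_equal(r1, cc$cor, tolerance = 1e-6)
})

test_that("permutation p-values are valid, deterministic, and detect identity", {
  set.seed(64)
  X <- matrix(rnorm(20 * 3), 20, 3)
  r1 <- ccaPermutationTest(X, X[, c(2, 1, 3)], nPerm = 99, seed = 3)
  expect_equal(r1@pValues[1], 1 / 100)  # nothing beats the identity pairing
  r2 <- ccaPermutationTest(X, X[, c(2, 1, 3)], nPerm = 99, seed = 3)
  expect_identical(r1@pValues, r2@pValues)
  Yind <- matrix(rnorm(20 * 3), 20, 3)
  r3 <- ccaPermutationTest(X, Yind, nPerm = 49, seed = 4)
  expect_true(all(r3@pValues >= 1 / 50 & r3@pValues <= 1))
  expect_error(ccaPermutationTest(X, Yind, nPerm = 0), "nPerm")
})

test_that("cross-modal feature pre-selection picks class-discriminatory columns", {
  ds <- generateDataset(quickConfig(seed = 65, effect_size = 1.5,
                                    protein_delta = 1.5))
  inp <- crossmodalInputs(ds$spectra, ds$proteins, topK = 6)
  expect_equal(dim(inp$X), c(26, 6))
  expect_equal(dim(inp$Y), c(26, 6))
  # planted proteins dominate the protein-side selection
  tr <- plantedTruth(quickConfig())
  expect_gt(mean(inp$y_ids %in% tr$affected_proteins), 0.5)
})

test_that("the autoencoder recovers a shared two-dimensional latent structure", {
  set.seed(66)
  n <- 26
  Z <- matrix(rnorm(n * 2), n, 2)
  X <- Z %*% matrix(rnorm(2 * 6), 2, 6)
  Y <- Z %*% matrix(rnorm(2 * 5), 2, 5)
  ae <- crossmodalAutoencoder(X, Y, widths = c(16L, 8L, 4L),
                              epochs = 3000, learningRate = 0.02, seed = 1)
  # inputs are standardized, so unit variance is the baseline error
  expect_lt(ae$final_loss_x, 0.2)
  expect_lt(ae$final_loss_y, 0.2)
  expect_equal(dim(ae$embedding), c(n, 2))
  # smoothed loss trajectory is non-increasing
  sm <- stats::filter(ae$loss, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-3))
})

test_that("zero-epoch training returns the seed-deterministic initialization", {
  set.seed(67)
  X <- matrix(rnorm(10 * 3), 10, 3)
  Y <- matrix(rnorm(10 * 3), 10, 3)
  a1 <- crossmodalAutoencoder(X, Y, widths = c(4L, 3L, 2L), epochs = 0,
                              seed = 9)
  a2 <- crossmodalAutoencoder(X, Y, widths = c(4L, 3L, 2L), epochs = 0,
                              seed = 9)
  expect_identical(a1$embedding, a2$embedding)
  a3 <- crossmodalAutoencoder(X, Y, widths = c(4L, 3L, 2L), epochs = 0,
                              seed = 10)
  expect_false(identical(a1$embedding, a3$embedding))
})

test_that("on null data the bottleneck separates classes no better than permuted labels", {
  # the autoencoder itself is label-blind, so on label-exchangeable inputs
  # its embedding must separate the true labels no better than permuted
  # ones; inputs are label-independent column draws (label-dependent
  # pre-selection would leak in-sample separation regardless of the
  # network - see the vignette)
  set.seed(600)
  excess <- sapply(1:4, function(i) {
    ds <- generateDataset(quickConfig(seed = 600 + i, effect_size = 0,
                                      protein_delta = 0))
    X <- averageReplicates(ds$spectra)[, sample(200, 5)]
    Y <- log(ratios(ds$proteins))[, sample(120, 5)]
    ae <- crossmodalAutoencoder(X, Y, widths = c(16L, 8L, 4L),
                                epochs = 400, learningRate = 0.02, seed = i)
    y <- classLabels(ds$spectra)
    sTrue <- embeddingSeparation(ae$embedding, y)
    sPerm <- mean(replicate(20,
      embeddingSeparation(ae$embedding, sample(y))))
    sTrue - sPerm
  })
  expect_lt(abs(mean(excess)), 0.15)
})
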