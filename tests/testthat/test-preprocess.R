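test_that("area normalization yields unit trapezoidal area and is idempotent", {
  w <- sort(runif(50, 400, 4000))
  set.seed(2)
  for (i in 1:5) {
    row <- abs(rnorm(50)) + 0.1
    out <- areaNormalize(row, w)
    trapz <- sum((out[-1] + out[-50]) * diff(w)) / 2
    expect_equal(trapz, 1, tolerance = 1e-12)
    expect_equal(areaNormalize(out, w), out, tolerance = 1e-12)
  }
  # constant row on a uniform grid of span W -> constant 1/W
  wu <- seq(0, 10, length.out = 11)
  expect_equal(areaNormalize(rep(5, 11), wu), rep(1 / 10, 11))
  expect_error(areaNormalize(rep(0, 11), wu), "area")
})

test_that("the internal-standard log-ratio matches hand computation and is scale-invariant", {
  w <- c(100, 200)
  expect_equal(alrKscn(c(2, 8), w, band = c(50, 150)), c(0, log(4)))
  # constant row equal to its band mean -> zeros
  expect_equal(alrKscn(rep(3, 5), 1:5, band = c(1, 5)), rep(0, 5))
  # global rescaling leaves the output unchanged
  set.seed(3)
  row <- abs(rnorm(64)) + 0.05
  wg <- seq(400, 4000, length.out = 64)
  expect_equal(alrKscn(row * 7.3, wg, c(2000, 2150)),
               alrKscn(row, wg, c(2000, 2150)), tolerance = 1e-12)
})

test_that("Savitzky-Golay reproduces low-order polynomials and matches a direct least-squares oracle", {
  x <- seq_len(41)
  poly <- 2 - 0.3 * x + 0.02 * x^2 + 0.001 * x^3
  expect_equal(savitzkyGolay(poly, 11, 3, 0), poly, tolerance = 1e-8)
  expect_equal(savitzkyGolay(rep(4, 31), 11, 3, 1), rep(0, 31),
               tolerance = 1e-10)
  # interior points equal an explicit per-window polynomial fit
  set.seed(4)
  row <- rnorm(41)
  sm <- savitzkyGolay(row, 11, 3, 0)
  for (i in c(6, 15, 30, 36)) {
    win <- (i - 5):(i + 5)
    fit <- lm(row[win] ~ poly(win, 3, raw = TRUE))
    expect_equal(sm[i], unname(predict(fit)[6]), tolerance = 1e-10)
  }
  expect_error(savitzkyGolay(row, 10, 3), "odd")
})

test_that("band removal deletes exactly the in-band channels in order", {
  g <- c(1000, 2050, 3000)
  out <- removeBand(c(1, 2, 3), g, c(2000, 2150))
  expect_equal(out$wavenumbers, c(1000, 3000))
  expect_equal(out$values, c(1, 3))
  # band outside the grid is the identity
  out2 <- removeBand(c(1, 2, 3), g, c(5000, 6000))
  expect_equal(out2$values, c(1, 2, 3))
  # counting oracle on random grids
  set.seed(5)
  for (i in 1:10) {
    gg <- sort(runif(100, 400, 4000))
    band <- sort(runif(2, 400, 4000))
    out3 <- removeBand(seq_len(100), gg, band)
    expect_length(out3$values, 100 - sum(gg >= band[1] & gg <= band[2]))
    expect_true(all(diff(out3$wavenumbers) > 0))
  }
  expect_error(removeBand(1:3, g, c(0, 1e5)), "every channel")
})

test_that("the DCT matches the direct formula, preserves energy, and inverts", {
  # brute-force double-loop oracle
  dctOracle <- function(x) {
    N <- length(x)
    vapply(0:(N - 1), function(k) {
      ck <- if (k == 0) 1 / sqrt(2) else 1
      sqrt(2 / N) * ck * sum(x * cos(pi / N * ((0:(N - 1)) + 0.5) * k))
    }, numeric(1))
  }
  set.seed(6)
  for (N in c(1, 2, 7, 32, 129)) {
    x <- rnorm(N)
    X <- dctTransform(x)
    expect_equal(X, dctOracle(x), tolerance = 1e-12)
    expect_equal(sum(X^2), sum(x^2), tolerance = 1e-10)   # Parseval
    expect_equal(inverseDct(X), x, tolerance = 1e-10)
  }
  expect_equal(dctTransform(rep(3, 4)), c(6, 0, 0, 0))    # X0 = c * sqrt(N)
  expect_error(dctTransform(numeric(0)), "empty")
})

test_that("frequency filtering drops requested and near-constant coefficients", {
  set.seed(7)
  M <- matrix(rnorm(8 * 10), 8, 10)
  M[, 4] <- 5                                  # planted zero-variance column
  out <- frequencyFilter(M, dropK = 0L)
  expect_equal(out$retained, setdiff(1:9, 3))  # k=0 dropped, k=3 constant
  expect_equal(out$coefficients, M[, -c(1, 4)])
  out2 <- frequencyFilter(M[, -4], dropK = integer())
  expect_equal(out2$retained, 0:8)             # nothing to drop -> identity
  expect_error(frequencyFilter(matrix(1, 5, 4), dropK = 0L), "every")
})

test_that("replicate averaging equals the explicit mean and handles errors", {
  ds <- toySpectra(nPairs = 2, C = 6)
  SL <- averageReplicates(ds)
  A <- absorbance(ds)
  s1 <- as.character(sampleInfo(ds)$sample_id[1])
  expect_equal(SL[s1, ], colMeans(A[replicateOf(ds) == s1, ]))
  # two known replicates average to their midpoint
  smp <- toySamples(2)
  A2 <- rbind(matrix(0, 1, 3), matrix(2, 1, 3),
              matrix(1, 6, 3))
  ds2 <- SpectralDataset(1:3, A2, c(smp$sample_id[1], smp$sample_id[1],
                                    rep(smp$sample_id[2:4], each = 2)), smp)
  expect_equal(unname(averageReplicates(ds2)[1, ]), rep(1, 3))
})

test_that("the preprocessing pipeline is deterministic and replicate-order invariant", {
  ds <- generateDataset(quickConfig(seed = 8))$spectra
  cfg <- runConfig()
  fm1 <- preprocessSpectra(ds, cfg)
  fm2 <- preprocessSpectra(ds, cfg)
  expect_identical(features(fm1), features(fm2))
  expect_equal(nrow(features(fm1)), 26)
  # permute replicate rows: sample-level output unchanged
  perm <- sample(nrow(absorbance(ds)))
  dsP <- SpectralDataset(wavenumbers(ds), absorbance(ds)[perm, ],
                         replicateOf(ds)[perm],
                         as.data.frame(sampleInfo(ds)))
  fmP <- preprocessSpectra(dsP, cfg)
  expect_equal(features(fmP), features(fm1), tolerance = 1e-12)
  # retained frequencies are recorded and exclude k = 0
  expect_false(0L %in% retainedIndices(fm1))
})
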