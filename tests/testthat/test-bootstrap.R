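test_that("AUROC matches pair enumeration, ties count half, symmetry holds", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.7, 0.8), c(1, 1, 0, 0)), 0.875)
  expect_equal(aurocScore(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  s <- rnorm(20); y <- rep(c(1, 0), 10)
  expect_equal(aurocScore(-s, y), 1 - aurocScore(s, y))
  expect_error(aurocScore(s, rep(1, 20)), "both classes")
  skip_if_not_installed("pROC")
  expect_equal(aurocScore(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))))
})

test_that("sensitivity/specificity tally the 2x2 table at the threshold", {
  expect_equal(sensSpec(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sensSpec(rep(0.4, 6), rep(c(1, 0), 3)),
               c(sensitivity = 0, specificity = 1))
  # 6-sample toy, hand-counted: TP=2 FN=1 TN=2 FP=1
  sc <- c(0.9, 0.6, 0.2, 0.7, 0.3, 0.1)
  yy <- c(1, 1, 1, 0, 0, 0)
  expect_equal(sensSpec(sc, yy), c(sensitivity = 2 / 3, specificity = 2 / 3))
})

test_that("sessions are deterministic in their seed", {
  ds <- generateDataset(quickConfig(seed = 30))$spectra
  cfg <- runConfig(bootstrap = list(resamples = 10L))
  fm <- preprocessSpectra(ds, cfg)
  flt <- filterFeatures(fm, threshold = 0.5)$filtered
  s1 <- runSession(flt, cfg, seed = 5L, B = 10, filterScope = "none")
  s2 <- runSession(flt, cfg, seed = 5L, B = 10, filterScope = "none")
  expect_identical(s1$metrics, s2$metrics)
  expect_identical(s1$selected, s2$selected)
  s3 <- runSession(flt, cfg, seed = 6L, B = 10, filterScope = "none")
  expect_false(identical(s1$metrics, s3$metrics))
  expect_true(all(as.matrix(s1$metrics) >= 0 & as.matrix(s1$metrics) <= 1))
})

test_that("separable data give near-perfect session AUROC", {
  smp <- toySamples(8)
  set.seed(31)
  X <- matrix(rnorm(16 * 5), 16, 5)
  X[, 1] <- X[, 1] + ifelse(smp$class == "FRI", 4, -4)
  fm <- FeatureMatrix(X, sprintf("f%d", 1:5), smp)
  s <- runSession(fm, runConfig(), seed = 2L, B = 20, filterScope = "none")
  expect_gt(s$m[["auroc"]], 0.95)
})

test_that("fixed-effect pooling matches hand-computed weighted means and CIs", {
  mk <- function(m, v, seed) structure(list(seed = seed, B = 10,
    metrics = NULL, m = c(auroc = m), v = c(auroc = v),
    selected = list(), redraws = 0L, fallbacks = 0L), class = "sessionResult")
  # identical sessions pool to themselves
  p1 <- poolSessions(list(mk(0.7, 1e-3, 1), mk(0.7, 1e-3, 2)))
  expect_equal(pooledEstimates(p1)$mean, 0.7)
  # equal variances pool to the arithmetic mean
  p2 <- poolSessions(list(mk(0.6, 2e-3, 1), mk(0.8, 2e-3, 2)))
  expect_equal(pooledEstimates(p2)$mean, 0.7)
  # unequal variances: inverse-variance weights, hand computation
  m <- c(0.6, 0.7, 0.8); v <- c(1e-3, 4e-3, 2e-3)
  p3 <- poolSessions(list(mk(m[1], v[1], 1), mk(m[2], v[2], 2),
                          mk(m[3], v[3], 3)))
  mu <- sum(m / v) / sum(1 / v); se <- 1 / sqrt(sum(1 / v))
  est <- pooledEstimates(p3)
  expect_equal(est$mean, mu, tolerance = 1e-12)
  expect_equal(est$ci_lo, mu - 1.96 * se, tolerance = 1e-12)
  expect_equal(est$ci_hi, mu + 1.96 * se, tolerance = 1e-12)
  expect_error(poolSessions(list(mk(0.7, 0, 1), mk(0.7, 1e-3, 2))),
               "degenerate")
  # agrees with a fixed-effect meta-analysis package
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = m, vi = v, method = "FE")
  expect_equal(mu, as.numeric(rma$beta), tolerance = 1e-10)
})

test_that("pooled CI width shrinks as sessions accumulate", {
  mk <- function(m, v, seed) structure(list(seed = seed, B = 10,
    metrics = NULL, m = c(auroc = m), v = c(auroc = v),
    selected = list(), redraws = 0L, fallbacks = 0L), class = "sessionResult")
  widths <- sapply(c(2, 5, 10, 20), function(S) {
    p <- poolSessions(lapply(seq_len(S), function(i) mk(0.7, 1e-3, i)))
    est <- pooledEstimates(p)
    est$ci_hi - est$ci_lo
  })
  expect_true(all(diff(widths) < 0))
})

test_that("selection frequencies are tallied over all resamples with stable ties", {
  mk <- function(sel, seed) structure(list(seed = seed, B = length(sel),
    metrics = NULL, m = c(auroc = 0.5), v = c(auroc = 1e-3),
    selected = sel, redraws = 0L, fallbacks = 0L), class = "sessionResult")
  sessions <- list(mk(list(c("a", "b"), c("a")), 1),
                   mk(list(c("a", "c"), character()), 2))
  r <- rankFeatures(sessions, topK = 2)
  expect_equal(r$feature[1], "a")
  expect_equal(r$frequency[1], 3 / 4)
  expect_equal(r$frequency[r$feature == "b"], 1 / 4)
  expect_identical(attr(r, "top"), c("a", "b"))   # b before c alphabetically
  expect_false("never" %in% attr(r, "top"))
})

test_that("across generator draws the honestly evaluated null centers at 0.5", {
  # per-dataset out-of-bag estimates scatter widely at n = 13 pairs, but
  # their expectation over datasets is 1/2 (in-resample screening scope)
  cfg <- runConfig(filter = list(scope = "resample"),
                   bootstrap = list(resamples = 15L))
  ms <- sapply(1:6, function(i) {
    ds <- generateDataset(quickConfig(seed = 300 + i, effect_size = 0))$spectra
    fm <- preprocessSpectra(ds, cfg)
    runSession(fm, cfg, seed = i, B = 15)$m[["auroc"]]
  })
  expect_lt(abs(mean(ms) - 0.5), 0.12)
})
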