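test_that("overwhelming regularization zeroes all coefficients", {
  inst <- randomInstance(30, 6, seed = 20)
  m <- enetFit(inst$X, inst$y, fitConfig(), lambda = 1e6)
  expect_equal(unname(coef(m)[-1]), rep(0, 6))
  expect_equal(m@intercept, qlogis(mean(inst$y)), tolerance = 1e-4)
  expect_length(selectedFeatures(m), 0)
})

test_that("a perfectly separating feature yields in-sample AUROC 1", {
  y <- rep(c(1, 0), each = 10)
  X <- cbind(sep = y * 2 - 1 + rnorm(20, 0, 0.01), noise = rnorm(20))
  m <- enetFit(X, y, fitConfig(lambda_min_ratio = 1e-4))
  expect_equal(aurocScore(predictProba(m, X), y), 1)
})

test_that("the fit matches an independent proximal-gradient oracle", {
  checked <- 0
  for (seed in 30:37) {
    inst <- randomInstance(24, 6, seed = seed)
    if (is.null(inst)) next
    lambda <- 0.05
    m <- enetFit(inst$X, inst$y, fitConfig(alpha = 0.5), lambda = lambda)
    orc <- istaEnet(inst$X, inst$y, lambda, alpha = 0.5)
    objM <- enetObjective(scale(inst$X) * sqrt(24 / 23), inst$y,
                          m@intercept, m@coefficients, lambda, 0.5)
    expect_lt(abs(objM - orc$objective), 1e-6)
    expect_lt(max(abs(m@coefficients - orc$beta)), 1e-4)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("the lasso and ridge limits agree with glmnet", {
  skip_if_not_installed("glmnet")
  for (alpha in c(0, 1)) {
    inst <- randomInstance(40, 5, seed = 41 + alpha)
    lambda <- 0.04
    m <- enetFit(inst$X, inst$y, fitConfig(alpha = alpha), lambda = lambda)
    g <- glmnet::glmnet(inst$X, inst$y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-14, intercept = TRUE)
    expect_lt(max(abs(m@coefficients - as.numeric(g$beta))), 1e-4)
    expect_lt(abs(m@intercept - as.numeric(g$a0)), 1e-4)
  }
})

test_that("the coordinate-descent objective never increases across sweeps", {
  inst <- randomInstance(30, 8, seed = 50)
  Xs <- scale(inst$X) * sqrt(30 / 29)
  tr <- ftirms:::.cpp_enet_single(Xs, inst$y, 0.02, 0.5, 1e-9, 5000L)$objective
  expect_true(all(diff(tr) <= 1e-10))
  expect_gt(length(tr), 2)
})

test_that("the solution is invariant to feature order", {
  inst <- randomInstance(30, 7, seed = 60)
  colnames(inst$X) <- sprintf("f%d", 1:7)
  m1 <- enetFit(inst$X, inst$y, fitConfig())
  perm <- c(4, 1, 7, 3, 2, 6, 5)
  m2 <- enetFit(inst$X[, perm], inst$y, fitConfig())
  expect_equal(coef(m1)[colnames(inst$X)], coef(m2)[colnames(inst$X)],
               tolerance = 1e-5)
})

test_that("predicted probabilities follow the logistic form and the cap holds", {
  # hand-computed logistic on a 2-feature toy
  m <- new("ElasticNetModel", intercept = 0.5, coefficients = c(1, -2),
           featureIds = c("a", "b"), lambda = 0.1, alpha = 0.5,
           center = c(0, 0), scale = c(1, 1), nonzeroCount = 2L,
           maxNonzero = 50L, path = list())
  X <- matrix(c(1, 0.5, -1, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predictProba(m, X), plogis(0.5 + X %*% c(1, -2))[, 1])
  expect_error(predictProba(m, matrix(0, 2, 2,
               dimnames = list(NULL, c("a", "zzz")))), "missing feature")
  # all-zero coefficients predict the constant prevalence
  inst <- randomInstance(30, 6, seed = 20)
  m0 <- enetFit(inst$X, inst$y, fitConfig(), lambda = 1e6)
  expect_equal(unname(predictProba(m0, inst$X)),
               rep(mean(inst$y), 30), tolerance = 1e-3)
  # nonzero count never exceeds the cap on a wide problem
  set.seed(70)
  Xw <- matrix(rnorm(26 * 200), 26, 200)
  yw <- rep(c(1, 0), each = 13)
  mw <- enetFit(Xw, yw, fitConfig(max_nonzero = 20L))
  expect_lte(mw@nonzeroCount, 20)
  expect_lte(length(selectedFeatures(mw)), 20)
})

test_that("degenerate inputs raise informative errors", {
  inst <- randomInstance(20, 4, seed = 80)
  expect_error(enetFit(inst$X, rep(1, 20)), "both classes")
  Xc <- inst$X; Xc[, 2] <- 3
  expect_error(enetFit(Xc, inst$y), "constant feature")
})
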